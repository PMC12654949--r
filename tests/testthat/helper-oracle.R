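# Independent oracles for the layering tests: exhaustive subset enumeration
# for the maximum non-crossing, one-pair-per-index subset, and a
# 2-colorability check of the conflict graph (minimum layer count <= 2).
# These deliberately share no code with the package's DP.

conflict_matrix <- function(pairs) {
  m <- nrow(pairs)
  conf <- matrix(FALSE, m, m)
  if (m >= 2L) {
    for (r in seq_len(m - 1L)) {
      for (s in seq(r + 1L, m)) {
        p <- pairs[r, ]
        q <- pairs[s, ]
        cf <- any(p %in% q) ||
          (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
          (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
        conf[r, s] <- conf[s, r] <- cf
      }
    }
  }
  conf
}

# maximum cardinality over all 2^m subsets with no pairwise conflict
bf_max_noncrossing <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(0L)
  stopifnot(m <= 20L)
  conf <- conflict_matrix(pairs)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  best <- 0L
  for (mask in seq_len(2L^m) - 1L) {
    idx <- which(bitwAnd(mask, bits) != 0L)
    if (length(idx) <= best) next
    if (!any(conf[idx, idx])) best <- length(idx)
  }
  best
}

# BFS 2-coloring of the conflict graph: TRUE iff the pair set splits into
# two planar layers
is_two_layerable <- function(pairs) {
  conf <- conflict_matrix(pairs)
  m <- nrow(conf)
  color <- rep(NA_integer_, m)
  for (s in seq_len(m)) {
    if (!is.na(color[s])) next
    color[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in which(conf[v, ])) {
        if (is.na(color[u])) {
          color[u] <- 1L - color[v]
          queue <- c(queue, u)
        } else if (color[u] == color[v]) return(FALSE)
      }
    }
  }
  TRUE
}

# random instance: n <= 30, <= max_pairs pairs; with share_endpoints = FALSE
# every index occurs in at most one pair (dot-bracket representable)
rand_pairs <- function(n, max_pairs = 12L, share_endpoints = FALSE) {
  if (share_endpoints) {
    m <- sample.int(max_pairs, 1L)
    ij <- t(sapply(seq_len(m), function(...) sort(sample.int(n, 2L) - 1L)))
    ij <- ij[!duplicated(paste(ij[, 1], ij[, 2])), , drop = FALSE]
  } else {
    k <- sample.int(min(max_pairs, n %/% 2L), 1L)
    pos <- sample.int(n, 2L * k) - 1L
    perm <- sample(2L * k)
    ij <- t(sapply(seq_len(k), function(t)
      sort(pos[perm[c(2L * t - 1L, 2L * t)]])))
  }
  ij
}

# decomposition invariant bundle used by property and acceptance tests
check_decomposition_invariants <- function(d, pairs) {
  sizes <- layer_sizes(d)
  # exact partition
  got <- do.call(rbind, d$layers)
  expect_setequal(paste(got[, 1], got[, 2]), paste(pairs[, 1], pairs[, 2]))
  expect_equal(nrow(got), nrow(pairs))
  # per-layer planarity + one pair per index
  for (lay in d$layers) {
    expect_false(any(duplicated(as.vector(lay))))
    if (nrow(lay) >= 2L) {
      cm <- conflict_matrix(lay)
      expect_false(any(cm))
    }
  }
  # non-increasing sizes
  expect_true(all(diff(sizes) <= 0L))
  # maximality witness: each pair in layer k >= 1 conflicts with every
  # earlier layer
  if (length(d$layers) >= 2L) {
    for (k in seq(2L, length(d$layers))) {
      for (r in seq_len(nrow(d$layers[[k]]))) {
        p <- d$layers[[k]][r, ]
        for (e in seq_len(k - 1L)) {
          earlier <- d$layers[[e]]
          conflicts <- vapply(seq_len(nrow(earlier)), function(s) {
            q <- earlier[s, ]
            any(p %in% q) ||
              (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
              (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
          }, logical(1))
          expect_true(any(conflicts))
        }
      }
    }
  }
  invisible(TRUE)
}
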