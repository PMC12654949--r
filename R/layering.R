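# Pseudoknot layer decomposition.
#
# A chain's pair set is mapped to 0-based sequential indices
# (indexed_pair_set), then decomposed by repeatedly extracting a
# maximum-cardinality non-crossing, one-pair-per-index subset with a
# Nussinov-style interval DP (O(n^3) time, O(n^2) space per pass) until no
# pairs remain. Layer 0 (core) is the first, largest extraction. The greedy
# layering does not guarantee the minimum number of layers.

MAX_LAYERS <- 26L  # safety cap; legitimate inputs stay far below

#' Build an indexed pair set
#'
#' Maps a chain-scoped pair table onto 0-based sequential residue indices,
#' the input representation of the layer decomposition. Residue identity is
#' (chain, author number, insertion code); author numbering gaps do not
#' create index gaps.
#'
#' @param pairs Pair data frame (single chain) or an integer matrix/2-column
#'   structure of 0-based index pairs.
#' @param residues Residue table (e.g. `chain$residues`) covering every
#'   residue in `pairs`; ignored when `pairs` is already an index matrix
#'   (a synthetic residue table is then built unless supplied).
#' @param n Sequence length, required when `pairs` is an index matrix and no
#'   residue table is given.
#' @param canonical Logical vector (recycled) of per-pair canonical flags;
#'   defaults to the `canonical` column when present, else TRUE.
#' @return An object of class `indexed_pair_set`: list with `n`, `pairs`
#'   (m x 2 integer matrix, 0-based, i < j), `canonical`, `index_map`
#'   (residue table ordered by `seq_index`).
#' @export
indexed_pair_set <- function(pairs, residues = NULL, n = NULL, canonical = NULL) {
  if (is.matrix(pairs) || (is.numeric(pairs) && is.null(dim(pairs)))) {
    mat <- matrix(as.integer(pairs), ncol = 2)
    if (is.null(residues)) {
      if (is.null(n)) kl_consistency_error("n required for index-matrix input")
      residues <- data.frame(chain_id = "A", seq_num = seq_len(n),
                             ins_code = "", res_name = "N",
                             seq_index = seq_len(n) - 1L,
                             stringsAsFactors = FALSE)
    }
    n <- n %||% nrow(residues)
    canonical <- rep_len(if (is.null(canonical)) TRUE else canonical,
                         nrow(mat))
  } else {
    stopifnot(is.data.frame(pairs))
    if (is.null(residues)) kl_consistency_error("residue table required for pair tables")
    rkey <- residue_key(residues$chain_id, residues$seq_num, residues$ins_code)
    i1 <- match(residue_key(pairs$chain1, pairs$seq1, pairs$ins1), rkey)
    i2 <- match(residue_key(pairs$chain2, pairs$seq2, pairs$ins2), rkey)
    if (anyNA(i1) || anyNA(i2))
      kl_consistency_error("pair references a residue absent from the residue table")
    mat <- cbind(residues$seq_index[i1], residues$seq_index[i2])
    n <- nrow(residues)
    canonical <- rep_len(if (is.null(canonical)) pairs$canonical %||% TRUE
                         else canonical, nrow(mat))
  }
  if (nrow(mat) > 0L) {
    swap <- mat[, 1] > mat[, 2]
    mat[swap, ] <- mat[swap, 2:1]
    if (any(mat[, 1] < 0L) || any(mat[, 2] >= n))
      kl_consistency_error("pair index out of range [0, n)")
    if (any(mat[, 1] == mat[, 2]))
      kl_consistency_error("self-pair (i, i) in indexed pair set")
    dup <- duplicated(paste(mat[, 1], mat[, 2]))
    if (any(dup)) {
      mat <- mat[!dup, , drop = FALSE]
      canonical <- canonical[!dup]
    }
  }
  structure(list(n = as.integer(n), pairs = mat,
                 canonical = as.logical(canonical),
                 index_map = residues[order(residues$seq_index), , drop = FALSE]),
            class = "indexed_pair_set")
}

#' @export
print.indexed_pair_set <- function(x, ...) {
  cat(sprintf("<indexed_pair_set> n = %d, %d pairs (%d canonical)\n",
              x$n, nrow(x$pairs), sum(x$canonical)))
  invisible(x)
}

#' Do two index pairs cross?
#'
#' Pairs (i, j) and (k, l) cross when i < k < j < l or k < i < l < j: drawn
#' as arcs on a line they intersect, so they cannot share a planar layer.
#' Sharing an endpoint is not crossing; that conflict is handled by the
#' one-pair-per-index structure of the DP.
#'
#' @param p,q Length-2 integer vectors (i, j) with i < j.
#' @return Logical scalar.
#' @export
pairs_cross <- function(p, q) {
  (p[1] < q[1] & q[1] < p[2] & p[2] < q[2]) |
  (q[1] < p[1] & p[1] < q[2] & q[2] < p[2])
}

# Conflict = crossing or shared endpoint (cannot share one layer).
pairs_conflict <- function(p, q) {
  any(p %in% q) || pairs_cross(p, q)
}

#' Maximum-cardinality non-crossing subset
#'
#' One Nussinov-style DP pass over the interval structure of the pair set.
#' Recurrence (1-based sequence positions, M\[i, j\] = best count using
#' positions i..j):
#' M\[i, j\] = max( M\[i+1, j\],
#'                  max over pairs (i, k), i < k <= j of
#'                      M\[i+1, k-1\] + M\[k+1, j\] + 1 ).
#' The traceback is deterministic: when scores tie, pairing position i is
#' preferred over leaving it unpaired, and the smallest partner k wins.
#'
#' @param ips An [indexed_pair_set()] (or m x 2 index matrix plus `n`).
#' @param n Sequence length when `ips` is a bare matrix.
#' @return Integer matrix (0-based index pairs) of a maximum subset with no
#'   crossing pairs and no shared indices.
#' @export
max_noncrossing_subset <- function(ips, n = NULL) {
  if (inherits(ips, "indexed_pair_set")) {
    mat <- ips$pairs; n <- ips$n
  } else {
    mat <- matrix(as.integer(ips), ncol = 2)
    if (is.null(n)) n <- max(mat) + 1L
  }
  m <- nrow(mat)
  if (m == 0L) return(matrix(integer(0), ncol = 2))
  p1 <- mat[, 1] + 1L  # 1-based
  p2 <- mat[, 2] + 1L
  # partners[[i]]: sorted k > i with (i, k) an allowed pair
  partners <- vector("list", n)
  for (r in seq_len(m)) partners[[p1[r]]] <- c(partners[[p1[r]]], p2[r])
  partners <- lapply(partners, function(v) if (is.null(v)) integer(0) else sort(v))
  M <- matrix(0L, nrow = n + 1L, ncol = n)  # M[i, j]; i > j rows stay 0
  val <- function(i, j) if (i > j) 0L else M[i, j]
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- M[i + 1L, j]
      ks <- partners[[i]]
      for (k in ks[ks <= j]) {
        v <- val(i + 1L, k - 1L) + val(k + 1L, j) + 1L
        if (v > best) best <- v
      }
      M[i, j] <- best
    }
  }
  # deterministic traceback
  sel <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i <= j) {
      target <- M[i, j]
      if (target == 0L) break
      paired <- FALSE
      ks <- partners[[i]]
      for (k in ks[ks <= j]) {
        if (val(i + 1L, k - 1L) + val(k + 1L, j) + 1L == target) {
          sel <- rbind(sel, c(i - 1L, k - 1L))
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  sel[order(sel[, 1]), , drop = FALSE]
}

#' Decompose a pair set into pseudoknot-free layers
#'
#' Repeatedly extracts a maximum-cardinality non-crossing subset
#' ([max_noncrossing_subset()]) and removes it, until no pairs remain.
#' Layers are recorded in extraction order: layer 0 (core) first. Greedy
#' maxima give non-increasing layer sizes; the number of layers is not
#' guaranteed minimal.
#'
#' @param ips An [indexed_pair_set()].
#' @param mode Selection mode label carried for downstream reporting
#'   (`"include_all"` or `"canonical_only"`); does not alter the algorithm.
#' @return An object of class `layer_decomposition`: list with `layers`
#'   (list of 0-based index matrices), `layer_id` (per input pair), `n`,
#'   `index_map`, `canonical`, `mode`.
#' @export
decompose_layers <- function(ips, mode = c("include_all", "canonical_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ips, "indexed_pair_set"))
  m <- nrow(ips$pairs)
  layer_id <- rep(NA_integer_, m)
  key_all <- paste(ips$pairs[, 1], ips$pairs[, 2])
  remaining <- seq_len(m)
  layers <- list()
  while (length(remaining) > 0L) {
    if (length(layers) >= MAX_LAYERS)
      kl_consistency_error(sprintf("layer cap (%d) exceeded; input malformed?", MAX_LAYERS))
    sub <- ips$pairs[remaining, , drop = FALSE]
    sel <- max_noncrossing_subset(sub, n = ips$n)
    hit <- remaining[match(paste(sel[, 1], sel[, 2]), key_all[remaining])]
    layer_id[hit] <- length(layers)
    layers[[length(layers) + 1L]] <- sel
    remaining <- setdiff(remaining, hit)
  }
  structure(list(layers = layers, layer_id = layer_id, n = ips$n,
                 index_map = ips$index_map, canonical = ips$canonical,
                 pairs = ips$pairs, mode = mode),
            class = "layer_decomposition")
}

#' @export
print.layer_decomposition <- function(x, ...) {
  sizes <- layer_sizes(x)
  cat(sprintf("<layer_decomposition> %d pairs in %d layer(s) [%s], pseudoknot order %d\n",
              nrow(x$pairs), length(x$layers), paste(sizes, collapse = ", "),
              pseudoknot_order(x)))
  invisible(x)
}

#' Layer sizes of a decomposition
#' @param d A `layer_decomposition`.
#' @return Integer vector of per-layer pair counts (layer 0 first).
#' @export
layer_sizes <- function(d) vapply(d$layers, nrow, integer(1))

#' Number of layers in a decomposition
#' @param d A `layer_decomposition`.
#' @return Integer count of layers (0 for an empty pair set).
#' @export
layer_count <- function(d) length(d$layers)

#' Pseudoknot order
#'
#' The number of layers beyond the core needed to accommodate all pairs:
#' `max(0, layer_count - 1)`. Zero means pseudoknot-free (purely nested or
#' empty).
#'
#' @param d A `layer_decomposition`.
#' @return Non-negative integer.
#' @export
pseudoknot_order <- function(d) max(0L, length(d$layers) - 1L)
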