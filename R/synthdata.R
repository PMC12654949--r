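# Ground-truthed synthetic fixtures: planted multi-layer pair sets,
# idealized duplex coordinates written as mmCIF/PDB, and annotator-output
# files (RNAView text, DSSR JSON). These stand in for downloaded structures
# in the test suite.
#
# Planted layout for k stems of sizes s_1 >= ... >= s_k: opener blocks
# O_1..O_k (1 unpaired gap between blocks and before the closers), then
# closer blocks C_1..C_k in the same order (2 unpaired gaps between closer
# blocks), then a 6-residue unpaired tail. Every pair of stem m crosses
# every pair of stem m' != m (all openers precede all closers and blocks
# keep their order), so the conflict graph is complete multipartite and the
# maximum non-crossing subset is exactly the largest stem. With strictly
# decreasing sizes the greedy decomposition therefore recovers the planted
# layering; with tied sizes the extraction order among tied stems is
# tie-break-dependent and only the size multiset is guaranteed.

#' Generate a planted multi-layer pair set
#'
#' Constructs mutually interleaved helical stems (stem m contributes nested
#' pairs (a_m + t, b_m - t)) positioned so that every stem crosses all
#' others, and returns the instance together with its ground-truth layering.
#' Sizes `c(3, 2)` with any seed give the canonical H-type instance on 20
#' residues: pairs (0,9), (1,8), (2,7) and (4,13), (5,12).
#'
#' @param layer_sizes Non-increasing integer vector of stem sizes
#'   (length <= 6, each >= 1).
#' @param seed Integer seed controlling residue identities only; the pair
#'   layout is deterministic in `layer_sizes`.
#' @param noncanonical_fraction Probability that a pair is relabelled with a
#'   non-canonical identity (A-G) and flagged non-canonical; may be a
#'   length-2 vector `c(core, noncore)` to plant an elevated non-canonical
#'   share outside the core.
#' @return An object of class `planted_instance`: `n`, `pairs` (0-based
#'   matrix), `layer_id` (planted layer per pair), `canonical`,
#'   `res_names` (length `n`), `layer_sizes`, `tied` (any equal sizes),
#'   `seed`.
#' @export
gen_planted_pairs <- function(layer_sizes, seed = 0L,
                              noncanonical_fraction = 0) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 1L || length(layer_sizes) > 6L ||
      any(layer_sizes < 1L) || is.unsorted(rev(layer_sizes)))
    kl_input_error("layer_sizes must be non-increasing, length 1..6, each >= 1")
  k <- length(layer_sizes)
  # opener blocks
  a <- integer(k); pos <- 0L
  for (m in seq_len(k)) {
    a[m] <- pos
    pos <- pos + layer_sizes[m] + 1L  # 1 gap after each opener block
  }
  # closer blocks (first closer block starts right after the mid gap)
  b <- integer(k)
  for (m in seq_len(k)) {
    b[m] <- pos + layer_sizes[m] - 1L  # outermost closer of stem m
    pos <- pos + layer_sizes[m] + 2L   # 2 gaps after each closer block
  }
  n <- pos - 2L + 6L  # drop trailing gap allowance, add 6-residue tail
  pairs <- do.call(rbind, lapply(seq_len(k), function(m) {
    t <- seq_len(layer_sizes[m]) - 1L
    cbind(a[m] + t, b[m] - t)
  }))
  layer_id <- rep(seq_len(k) - 1L, layer_sizes)
  m_pairs <- nrow(pairs)
  frac <- rep_len(noncanonical_fraction, 2L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  canonical <- rep(TRUE, m_pairs)
  p_non <- ifelse(layer_id == 0L, frac[1], frac[2])
  canonical[stats::runif(m_pairs) < p_non] <- FALSE
  # residue identities: canonical pairs get complementary bases, the rest A-G
  res_names <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  for (r in seq_len(m_pairs)) {
    if (canonical[r]) {
      duo <- sample(list(c("G", "C"), c("C", "G"), c("A", "U"),
                         c("U", "A"), c("G", "U"), c("U", "G")), 1L)[[1]]
    } else {
      duo <- c("A", "G")
    }
    res_names[pairs[r, 1] + 1L] <- duo[1]
    res_names[pairs[r, 2] + 1L] <- duo[2]
  }
  structure(list(n = n, pairs = pairs, layer_id = layer_id,
                 canonical = canonical, res_names = res_names,
                 layer_sizes = layer_sizes,
                 tied = anyDuplicated(layer_sizes) > 0L, seed = seed),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("<planted_instance> n = %d, %d pairs in %d planted layer(s) [%s]\n",
              x$n, nrow(x$pairs), length(x$layer_sizes),
              paste(x$layer_sizes, collapse = ", ")))
  invisible(x)
}

#' Indexed pair set of a planted instance
#'
#' @param instance A `planted_instance`.
#' @param mode `"include_all"` (all planted pairs) or `"canonical_only"`.
#' @return An [indexed_pair_set()].
#' @export
planted_ips <- function(instance, mode = c("include_all", "canonical_only")) {
  mode <- match.arg(mode)
  keep <- if (mode == "canonical_only") instance$canonical
          else rep(TRUE, nrow(instance$pairs))
  residues <- data.frame(chain_id = "A", seq_num = seq_len(instance$n),
                         ins_code = "", res_name = instance$res_names,
                         seq_index = seq_len(instance$n) - 1L,
                         stringsAsFactors = FALSE)
  indexed_pair_set(instance$pairs[keep, , drop = FALSE], residues = residues,
                   canonical = instance$canonical[keep])
}

# Coordinates for an idealized (schematic, not stereochemical) structure:
# each planted pair occupies its own cluster 50 A from the others, with
# C1'-C1' = 10.4 A and WC-edge N...N = 3.0 A (inside the detector windows);
# unpaired residues sit > 20 A from everything on a separate line.
planted_coordinates <- function(instance) {
  n <- instance$n
  res_names <- instance$res_names
  parents <- parent_base(res_names)
  c1 <- matrix(NA_real_, n, 3)
  wc <- matrix(NA_real_, n, 3)
  m_pairs <- nrow(instance$pairs)
  for (r in seq_len(m_pairs)) {
    i <- instance$pairs[r, 1] + 1L
    j <- instance$pairs[r, 2] + 1L
    x0 <- (r - 1L) * 50
    c1[i, ] <- c(x0, 0, 0);        wc[i, ] <- c(x0 + 3.7, 0, 0)
    c1[j, ] <- c(x0 + 10.4, 0, 0); wc[j, ] <- c(x0 + 6.7, 0, 0)
  }
  unp <- which(is.na(c1[, 1]))
  for (u in seq_along(unp)) {
    i <- unp[u]
    c1[i, ] <- c((u - 1L) * 50, 1000, 0)
    wc[i, ] <- c((u - 1L) * 50 + 1.5, 1000, 0)
  }
  list(c1 = c1, wc = wc,
       wc_atom = ifelse(is.na(parents), "N1", wc_edge_atom(parents)))
}

#' Write a planted instance as an idealized structure file
#'
#' Writes a single-chain structure (chain A, author numbers 1..n) whose
#' paired residues' C1' and Watson-Crick-edge nitrogen atoms sit inside the
#' built-in detector's acceptance windows, and whose unpaired residues are
#' far from any partner. Geometry is schematic, sufficient for exercising
#' I/O and detection contracts, not stereochemically realistic A-form.
#' Pairs with sequence separation <= 2 are below the detector's separation
#' floor and will not be recovered.
#'
#' @param instance A `planted_instance`.
#' @param path Output file path.
#' @param format `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
gen_helix_structure <- function(instance, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  geo <- planted_coordinates(instance)
  n <- instance$n
  lines <- character(0)
  if (format == "mmcif") {
    lines <- c("data_synthetic_helix",
               "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.label_atom_id", "_atom_site.label_alt_id",
               "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy")
    aid <- 0L
    for (i in seq_len(n)) {
      for (atom in c("C1'", geo$wc_atom[i])) {
        xyz <- if (atom == "C1'") geo$c1[i, ] else geo$wc[i, ]
        aid <- aid + 1L
        lines <- c(lines, sprintf("ATOM %d \"%s\" . %s A %d ? %.3f %.3f %.3f 1.00",
                                  aid, atom, instance$res_names[i], i,
                                  xyz[1], xyz[2], xyz[3]))
      }
    }
    lines <- c(lines, "#")
  } else {
    aid <- 0L
    for (i in seq_len(n)) {
      for (atom in c("C1'", geo$wc_atom[i])) {
        xyz <- if (atom == "C1'") geo$c1[i, ] else geo$wc[i, ]
        aid <- aid + 1L
        lines <- c(lines, sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                                  aid, atom, instance$res_names[i], "A", i,
                                  xyz[1], xyz[2], xyz[3]))
      }
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gen_helix_structure
#' @export
gen_helix_mmcif <- function(instance, path) gen_helix_structure(instance, path, "mmcif")

#' Write an RNAView-style annotation fixture
#'
#' Serializes a planted instance's pair list in RNAView base-pair line
#' format (canonical pairs as `"+/+ cis"`, non-canonical as `"H/W tran"`),
#' for parser tests.
#'
#' @param instance A `planted_instance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gen_rnaview_file <- function(instance, path) {
  lines <- "BASE_PAIR:"
  for (r in seq_len(nrow(instance$pairs))) {
    i <- instance$pairs[r, 1] + 1L
    j <- instance$pairs[r, 2] + 1L
    ann <- if (instance$canonical[r]) "+/+ cis         XIX" else "H/W tran        !1H(b_b)"
    lines <- c(lines, sprintf("%6d_%d, A: %5d %s-%s %5d A: %s",
                              i, j, i, instance$res_names[i],
                              instance$res_names[j], j, ann))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a DSSR-JSON-style annotation fixture
#'
#' Serializes a planted instance's pair list as a DSSR-like JSON `pairs`
#' array (`nt1`/`nt2` in `chain.resname+number` form; `name` WC / Wobble /
#' Hoogsteen), for parser tests.
#'
#' @inheritParams gen_rnaview_file
#' @return `path`, invisibly.
#' @export
gen_dssr_file <- function(instance, path) {
  entries <- lapply(seq_len(nrow(instance$pairs)), function(r) {
    i <- instance$pairs[r, 1] + 1L
    j <- instance$pairs[r, 2] + 1L
    id <- sort(c(instance$res_names[i], instance$res_names[j]))
    nm <- if (!instance$canonical[r]) "Hoogsteen"
          else if (identical(id, c("G", "U"))) "Wobble" else "WC"
    list(nt1 = sprintf("A.%s%d", instance$res_names[i], i),
         nt2 = sprintf("A.%s%d", instance$res_names[j], j),
         bp = sprintf("%s-%s", instance$res_names[i], instance$res_names[j]),
         name = nm, LW = if (nm == "Hoogsteen") "tHW" else "cWW")
  })
  jsonlite::write_json(list(pairs = entries), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic corpus of planted instances
#'
#' Samples per-chain layer-size profiles concentrated on 1-3 layers (most
#' real chains have few layers; layer-count probabilities 0.55 / 0.30 /
#' 0.10 / 0.05 for 1..4 layers), with strictly decreasing stem sizes so the
#' greedy decomposition provably recovers the planted layering. A stated
#' fraction of pairs is relabelled non-canonical, preferentially outside the
#' core (10% core, 50% non-core).
#'
#' @param num_chains Number of instances (>= 1).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return List of `planted_instance`s.
#' @export
gen_corpus <- function(num_chains, seed = 1L) {
  if (num_chains < 1L) kl_input_error("num_chains must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  profiles <- lapply(seq_len(num_chains), function(i) {
    L <- sample(1:4, 1L, prob = c(0.55, 0.30, 0.10, 0.05))
    sort(sample(2:12, L), decreasing = TRUE)  # distinct => strictly decreasing
  })
  seeds <- sample.int(1e6, num_chains)
  lapply(seq_len(num_chains), function(i)
    gen_planted_pairs(profiles[[i]], seed = seeds[i],
                      noncanonical_fraction = c(0.10, 0.50)))
}
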