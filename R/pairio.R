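# Base-pair ingestion and classification.
#
# Pairs arrive from three sources: RNAView base-pair text output, DSSR JSON
# output (both parsed, never executed), and a built-in geometric detector for
# canonical pairs. All sources normalize to one pair table (data frame) with
# columns chain1/seq1/ins1/name1, chain2/seq2/ins2/name2, geometry_class,
# canonical, source.

# Parent-identity mapping: modified nucleotides fold to A/C/G/U for the
# canonical-identity test. Extensible via the `parent_map` argument of
# classify_canonical(). Codes not listed (and not plain A/C/G/U) are never
# canonical.
DEFAULT_PARENT_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  PSU = "U", "5MU" = "U", H2U = "U", "4SU" = "U", UR3 = "U", DHU = "U",
  "1MA" = "A", "2MA" = "A", A2M = "A", MIA = "A",
  "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", "1MG" = "G", G7M = "G",
  OMC = "C", "5MC" = "C", "4OC" = "C", C5M = "C")

parent_base <- function(res_name, parent_map = DEFAULT_PARENT_MAP) {
  out <- unname(parent_map[toupper(res_name)])
  out
}

#' Classify a base pair as canonical
#'
#' Canonical pairs are Watson-Crick A-U and G-C plus wobble G-U, in cis
#' Watson-Crick geometry as reported by the source annotator. Identity alone
#' is not sufficient by default: a G.C Hoogsteen pair is non-canonical. Set
#' `require_cis_wc = FALSE` to classify on identity only.
#'
#' @param res_name1,res_name2 Residue codes (order irrelevant); modified
#'   nucleotides are folded to their parent base via `parent_map`.
#' @param geometry_class Annotator geometry label: RNAView edge/orientation
#'   (`"+/+"`, `"-/-"`, `"W/W cis"`, `"H/W tran"`, ...), DSSR pair name
#'   (`"WC"`, `"Wobble"`, `"Hoogsteen"`, ...), or `"builtin"`.
#' @param source One of `"RNAView"`, `"DSSR"`, `"builtin"`.
#' @param require_cis_wc Require cis Watson-Crick geometry (default TRUE).
#' @param parent_map Named character vector mapping residue codes to parent
#'   bases A/C/G/U.
#' @return Logical scalar (vectorized over its residue/geometry arguments).
#' @export
classify_canonical <- function(res_name1, res_name2, geometry_class, source,
                               require_cis_wc = TRUE,
                               parent_map = DEFAULT_PARENT_MAP) {
  b1 <- parent_base(res_name1, parent_map)
  b2 <- parent_base(res_name2, parent_map)
  ident <- ifelse(is.na(b1) | is.na(b2), "",
                  paste0(pmin(b1, b2), pmax(b1, b2)))
  id_ok <- ident %in% c("AU", "CG", "GU")
  if (!require_cis_wc) return(id_ok)
  geo_ok <- mapply(is_cis_wc_geometry, geometry_class, source, USE.NAMES = FALSE)
  id_ok & geo_ok
}

is_cis_wc_geometry <- function(geometry_class, source) {
  g <- tolower(trimws(geometry_class))
  src <- tolower(source)
  if (src == "builtin") return(TRUE)
  if (src == "rnaview") {
    if (startsWith(g, "+/+") || startsWith(g, "-/-")) return(TRUE)
    if (grepl("^w/w\\s+cis", g)) return(TRUE)
    if (!grepl("^[+w.-]/[+w.-]|cis|tran|syn|stacked", g))
      warn_once(paste0("rnaview:", g),
                sprintf("unknown RNAView geometry label '%s' treated as non-canonical",
                        geometry_class))
    return(FALSE)
  }
  if (src == "dssr") {
    if (g %in% c("wc", "wobble")) return(TRUE)
    known <- c("hoogsteen", "rhoogsteen", "sheared", "imino", "calcutta",
               "platform", "~wobble", "~sheared", "--")
    if (!g %in% known)
      warn_once(paste0("dssr:", g),
                sprintf("unknown DSSR pair name '%s' treated as non-canonical",
                        geometry_class))
    return(FALSE)
  }
  warn_once(paste0("source:", src),
            sprintf("unknown annotator source '%s' treated as non-canonical", source))
  FALSE
}

#' Parse RNAView base-pair output
#'
#' Reads the base-pair section of RNAView text output. Each pair line carries
#' the position pair, chain ids, author residue numbers, residue names, and
#' an edge/orientation annotation such as `"+/+ cis"` or `"W/W tran"`.
#' Lines RNAView marks as stacked carry no pairing class and are skipped.
#' Inter-chain pairs are retained (filtering happens in [select_pairs()]).
#'
#' @param text Character vector of lines, or a single string.
#' @param require_cis_wc Passed to [classify_canonical()].
#' @return Pair data frame (one row per parsed pair line).
#' @export
parse_rnaview <- function(text, require_cis_wc = TRUE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  # e.g. "    1_20, A:     1 G-C    20 A: +/+ cis         XIX"
  pat <- paste0("^\\s*(\\d+)_(\\d+),\\s+(\\S+):\\s+(-?\\d+)([A-Za-z]?)\\s+",
                "(\\S+)-(\\S+)\\s+(-?\\d+)([A-Za-z]?)\\s+(\\S+):\\s*(.*)$")
  hit <- grepl(pat, lines)
  candidates <- grepl("^\\s*\\d+_\\d+,", lines)
  if (!any(hit)) {
    first_bad <- if (any(candidates)) lines[candidates][1] else lines[nzchar(trimws(lines))][1]
    kl_format_error(sprintf("no parseable RNAView pair lines (first candidate: '%s')",
                            first_bad %||% "<empty input>"))
  }
  m <- regmatches(lines[hit], regexec(pat, lines[hit]))
  rows <- lapply(m, function(g) {
    ann <- trimws(g[12])
    data.frame(chain1 = g[4], seq1 = as.integer(g[5]), ins1 = g[6],
               name1 = g[7], chain2 = g[11], seq2 = as.integer(g[9]),
               ins2 = g[10], name2 = g[8], geometry_class = ann,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  # geometry_class: first token (+ optional cis/tran); drop Saenger roman tag
  gtok <- regmatches(pairs$geometry_class,
                     regexec("^(\\S+)(\\s+(cis|tran))?", pairs$geometry_class))
  pairs$geometry_class <- vapply(gtok, function(g) trimws(paste(g[2], g[4])), "")
  stacked <- grepl("stacked", pairs$geometry_class, ignore.case = TRUE)
  pairs <- pairs[!stacked, , drop = FALSE]
  if (nrow(pairs) == 0L)
    kl_format_error("RNAView output contains only stacked lines, no base pairs")
  pairs$canonical <- classify_canonical(pairs$name1, pairs$name2,
                                        pairs$geometry_class, "RNAView",
                                        require_cis_wc = require_cis_wc)
  pairs$source <- "RNAView"
  normalize_pairs(pairs)
}

# DSSR nt id: [pdbid-]chain.resname+number[^inscode], e.g. "A.G15^B", "B.5MU54"
parse_dssr_ntid <- function(ntid) {
  parts <- strsplit(ntid, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  chain <- parts[length(parts) - 1L]
  body <- parts[length(parts)]
  m <- regexec("^(.+?)(-?\\d+)(\\^(.))?$", body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L) return(NULL)
  list(chain = chain, name = g[2], num = as.integer(g[3]),
       ins = if (is.na(g[5]) || g[5] == "") "" else g[5])
}

#' Parse DSSR JSON output
#'
#' Reads the `pairs` array of DSSR's JSON output. Each entry carries `nt1`
#' and `nt2` identifiers in `chain.resname+number[^inscode]` form and a
#' `name` field (`"WC"`, `"Wobble"`, `"Hoogsteen"`, ...) used as the
#' geometry class. Entries missing `nt1`/`nt2` are skipped with a warning.
#'
#' @param text DSSR JSON text (string or character vector of lines).
#' @param require_cis_wc Passed to [classify_canonical()].
#' @return Pair data frame (possibly empty when the pairs array is empty).
#' @export
parse_dssr <- function(text, require_cis_wc = TRUE) {
  txt <- paste(text, collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    kl_format_error(sprintf("malformed DSSR JSON: %s", conditionMessage(e))))
  entries <- obj$pairs %||% list()
  rows <- list()
  for (e in entries) {
    if (is.null(e$nt1) || is.null(e$nt2)) {
      warning("DSSR pair entry missing nt1/nt2 skipped", call. = FALSE)
      next
    }
    r1 <- parse_dssr_ntid(e$nt1); r2 <- parse_dssr_ntid(e$nt2)
    if (is.null(r1) || is.null(r2)) {
      warning(sprintf("unparseable DSSR nt id in entry (%s, %s); skipped",
                      e$nt1, e$nt2), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = r1$chain, seq1 = r1$num, ins1 = r1$ins, name1 = r1$name,
      chain2 = r2$chain, seq2 = r2$num, ins2 = r2$ins, name2 = r2$name,
      geometry_class = as.character(e$name %||% ""), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_pair_df())
  pairs <- do.call(rbind, rows)
  pairs$canonical <- classify_canonical(pairs$name1, pairs$name2,
                                        pairs$geometry_class, "DSSR",
                                        require_cis_wc = require_cis_wc)
  pairs$source <- "DSSR"
  normalize_pairs(pairs)
}

# Geometry envelopes of the built-in detector (Angstrom): Watson-Crick-edge
# nitrogen distance and C1'-C1' distance of a canonical pair.
BUILTIN_NN_MAX <- 3.2
BUILTIN_C1_RANGE <- c(9.8, 11.0)
BUILTIN_MIN_SEP <- 3L  # j - i > 2 in seq_index

wc_edge_atom <- function(parent) ifelse(parent %in% c("A", "G"), "N1", "N3")

#' Detect canonical base pairs from coordinates
#'
#' Fallback annotator so the pipeline runs without RNAView/DSSR. Reports a
#' pair (i, j), j > i + 2 in sequential index, when the residue identities
#' form a canonical combination (A-U, G-C, G-U after parent mapping) and the
#' geometry passes standard canonical-pair envelopes: Watson-Crick-edge
#' N...N distance <= 3.2 A and C1'-C1' distance in [9.8, 11.0] A. Only
#' canonical pairs are detectable by construction. Residues missing C1' or
#' the WC-edge nitrogen are skipped with a warning.
#'
#' @param chain A [chain_structure].
#' @return Pair data frame with `geometry_class = "builtin"`,
#'   `canonical = TRUE`.
#' @export
detect_pairs_builtin <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  n <- nrow(res)
  if (n == 0L) return(empty_pair_df())
  parents <- parent_base(res$res_name)
  coords <- function(atom_name) {
    idx <- match(paste(res$seq_index, atom_name),
                 paste(chain$atoms$seq_index, chain$atoms$atom))
    cbind(chain$atoms$x[idx], chain$atoms$y[idx], chain$atoms$z[idx])
  }
  c1 <- coords(NUCLEOTIDE_ATOM)
  wc <- matrix(NA_real_, n, 3)
  for (a in c("N1", "N3")) {
    pick <- !is.na(parents) & wc_edge_atom(parents) == a
    if (any(pick)) wc[pick, ] <- coords(a)[pick, , drop = FALSE]
  }
  usable <- !is.na(parents) & !is.na(c1[, 1]) & !is.na(wc[, 1])
  skipped <- which(!usable & !is.na(parents))
  if (length(skipped) > 0L)
    warning(sprintf("chain %s: %d residue(s) missing C1'/WC-edge atoms skipped",
                    chain$chain_id, length(skipped)), call. = FALSE)
  ok <- which(usable)
  rows <- list()
  for (ii in seq_along(ok)) {
    i <- ok[ii]
    for (j in ok[ok >= i + BUILTIN_MIN_SEP]) {
      ident <- paste0(min(parents[i], parents[j]), max(parents[i], parents[j]))
      if (!ident %in% c("AU", "CG", "GU")) next
      dnn <- sqrt(sum((wc[i, ] - wc[j, ])^2))
      if (dnn > BUILTIN_NN_MAX) next
      dc1 <- sqrt(sum((c1[i, ] - c1[j, ])^2))
      if (dc1 < BUILTIN_C1_RANGE[1] || dc1 > BUILTIN_C1_RANGE[2]) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain1 = res$chain_id[i], seq1 = res$seq_num[i], ins1 = res$ins_code[i],
        name1 = res$res_name[i], chain2 = res$chain_id[j], seq2 = res$seq_num[j],
        ins2 = res$ins_code[j], name2 = res$res_name[j],
        geometry_class = "builtin", canonical = TRUE, source = "builtin",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_pair_df())
  normalize_pairs(do.call(rbind, rows))
}

#' Select pairs for one chain
#'
#' Keeps intra-chain pairs of the requested chain; `canonical_only`
#' additionally drops non-canonical pairs. Duplicate annotations of the same
#' residue pair collapse to one, preferring the canonical annotation.
#'
#' @param pairs Pair data frame from any parser/detector.
#' @param chain_id Author chain id to keep.
#' @param mode `"canonical_only"` or `"include_all"`.
#' @return Filtered pair data frame; empty (with a warning) when the chain
#'   has no pairs.
#' @export
select_pairs <- function(pairs, chain_id, mode = c("canonical_only", "include_all")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L || !chain_id %in% c(pairs$chain1, pairs$chain2)) {
    warning(sprintf("chain '%s' absent from pair list", chain_id), call. = FALSE)
    return(empty_pair_df())
  }
  keep <- pairs$chain1 == chain_id & pairs$chain2 == chain_id
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    key <- paste(residue_key(out$chain1, out$seq1, out$ins1),
                 residue_key(out$chain2, out$seq2, out$ins2))
    # canonical annotation wins among duplicates
    out <- out[order(key, !out$canonical), , drop = FALSE]
    out <- out[!duplicated(paste(residue_key(out$chain1, out$seq1, out$ins1),
                                 residue_key(out$chain2, out$seq2, out$ins2))), ,
               drop = FALSE]
  }
  if (mode == "canonical_only") out <- out[out$canonical, , drop = FALSE]
  if (nrow(out) == 0L)
    warning(sprintf("no pairs on chain '%s' under mode '%s'", chain_id, mode),
            call. = FALSE)
  rownames(out) <- NULL
  out
}
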