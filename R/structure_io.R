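# Structure readers: PDB (fixed columns) and mmCIF (atom_site loop).
# A chain_structure carries the ordered residue table of one chain plus the
# atom coordinates the built-in pair detector needs (C1' and the
# Watson-Crick-edge nitrogen, N1 for purines / N3 for pyrimidines).

#' Construct a chain structure
#'
#' Container for one nucleotide chain: ordered residues (author numbering,
#' 0-based `seq_index` assigned in file order) plus per-residue atom
#' coordinates in Angstrom.
#'
#' @param chain_id Author chain identifier.
#' @param residues Data frame with columns `chain_id`, `seq_num`, `ins_code`,
#'   `res_name`, `seq_index`.
#' @param atoms Data frame with columns `seq_index`, `atom`, `x`, `y`, `z`.
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, residues, atoms) {
  stopifnot(is.character(chain_id), nzchar(chain_id))
  residues$seq_index <- seq_len(nrow(residues)) - 1L
  structure(list(chain_id = chain_id, residues = residues, atoms = atoms),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s: %d residues, %d atoms\n",
              x$chain_id, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

# Residues are treated as nucleotides when they carry a ribose C1' atom;
# this avoids maintaining a residue-name whitelist and keeps modified
# nucleotides (PSU, 5MC, ...) in the chain.
NUCLEOTIDE_ATOM <- "C1'"

#' Read an RNA structure file
#'
#' Parses a PDB or mmCIF file into one [chain_structure] per chain that
#' contains at least one nucleotide residue (identified by the presence of a
#' C1' atom). Residue order and author numbering are preserved; alternate
#' location duplicates collapse to the first-listed conformer; non-nucleotide
#' chains are omitted.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` detects from
#'   the file extension, falling back to content sniffing.
#' @return Named list of [chain_structure] objects (names = chain ids).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) kl_input_error(sprintf("cannot read structure file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(startsWith(lines, "loop_")) || any(startsWith(lines, "data_"))) "mmcif"
      else "pdb"
  }
  atoms <- switch(format,
    pdb = parse_pdb_atoms(lines, path),
    mmcif = parse_mmcif_atoms(lines, path))
  if (nrow(atoms) == 0L)
    kl_format_error(sprintf("no ATOM records found in '%s'", path))
  chains <- build_chains(atoms)
  if (length(chains) == 0L)
    kl_empty_error(sprintf("no nucleotide chains in '%s'", path))
  chains
}

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  # stop at first ENDMDL so multi-model files use model 1 only
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0L) keep[seq_along(keep) > endm[1]] <- FALSE
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_atom_df())
  df <- data.frame(
    atom = gsub("\\*", "'", trimws(substr(lines, 13, 16))),
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain_id = trimws(substr(lines, 22, 22)),
    seq_num = suppressWarnings(as.integer(substr(lines, 23, 26))),
    ins_code = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
  if (anyNA(df$seq_num) || anyNA(df$x))
    kl_format_error(sprintf("malformed ATOM record in '%s'", path))
  df
}

empty_atom_df <- function() {
  data.frame(atom = character(0), altloc = character(0),
             res_name = character(0), chain_id = character(0),
             seq_num = integer(0), ins_code = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             stringsAsFactors = FALSE)
}

# Tokenize one mmCIF data row, honoring single/double quoted values.
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_mmcif_atoms <- function(lines, path) {
  # locate the atom_site loop
  li <- which(trimws(lines) == "loop_")
  block <- NULL
  for (s in li) {
    j <- s + 1L
    fields <- character(0)
    while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1L
    }
    if (any(startsWith(fields, "_atom_site."))) { block <- list(start = j, fields = fields); break }
  }
  if (is.null(block)) return(empty_atom_df())
  fields <- sub("^_atom_site\\.", "", block$fields)
  rows <- list(); j <- block$start
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") || ln == "loop_" ||
        startsWith(ln, "data_")) break
    toks <- cif_tokens(lines[j])
    if (length(toks) != length(fields))
      kl_format_error(sprintf("mmCIF atom_site row with %d tokens (expected %d) in '%s'",
                              length(toks), length(fields), path))
    rows[[length(rows) + 1L]] <- toks
    j <- j + 1L
  }
  if (length(rows) == 0L) return(empty_atom_df())
  mat <- do.call(rbind, rows)
  colnames(mat) <- fields
  get_col <- function(primary, fallback = NULL) {
    if (primary %in% fields) return(mat[, primary])
    if (!is.null(fallback) && fallback %in% fields) return(mat[, fallback])
    kl_format_error(sprintf("mmCIF atom_site lacks %s in '%s'", primary, path))
  }
  grp <- if ("group_PDB" %in% fields) mat[, "group_PDB"] else rep("ATOM", nrow(mat))
  ins <- if ("pdbx_PDB_ins_code" %in% fields) mat[, "pdbx_PDB_ins_code"] else rep("", nrow(mat))
  ins[ins %in% c("?", ".")] <- ""
  alt <- if ("label_alt_id" %in% fields) mat[, "label_alt_id"] else rep("", nrow(mat))
  alt[alt %in% c("?", ".")] <- ""
  df <- data.frame(
    atom = gsub("\\*", "'", get_col("label_atom_id", "auth_atom_id")),
    altloc = alt,
    res_name = get_col("auth_comp_id", "label_comp_id"),
    chain_id = get_col("auth_asym_id", "label_asym_id"),
    seq_num = suppressWarnings(as.integer(get_col("auth_seq_id", "label_seq_id"))),
    ins_code = ins,
    x = as.numeric(get_col("Cartn_x")),
    y = as.numeric(get_col("Cartn_y")),
    z = as.numeric(get_col("Cartn_z")),
    stringsAsFactors = FALSE)
  df <- df[grp %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (anyNA(df$seq_num) || anyNA(df$x))
    kl_format_error(sprintf("malformed atom_site values in '%s'", path))
  df
}

# Group atoms into per-chain residue tables; collapse altlocs to the
# first-listed conformer; keep only chains with >= 1 nucleotide residue.
build_chains <- function(atoms) {
  # altloc collapse: keep first atom per (chain, residue, atom name)
  akey <- paste(residue_key(atoms$chain_id, atoms$seq_num, atoms$ins_code),
                atoms$atom, sep = "|")
  atoms <- atoms[!duplicated(akey), , drop = FALSE]
  chains <- list()
  for (cid in unique(atoms$chain_id)) {
    ca <- atoms[atoms$chain_id == cid, , drop = FALSE]
    rkey <- residue_key(ca$chain_id, ca$seq_num, ca$ins_code)
    first <- !duplicated(rkey)
    res <- data.frame(chain_id = ca$chain_id[first], seq_num = ca$seq_num[first],
                      ins_code = ca$ins_code[first], res_name = ca$res_name[first],
                      stringsAsFactors = FALSE)
    res$seq_index <- seq_len(nrow(res)) - 1L
    # nucleotide = residue owning a C1' atom
    has_c1 <- unique(rkey[ca$atom == NUCLEOTIDE_ATOM])
    nt <- residue_key(res$chain_id, res$seq_num, res$ins_code) %in% has_c1
    if (!any(nt)) next
    res <- res[nt, , drop = FALSE]
    res$seq_index <- seq_len(nrow(res)) - 1L
    idx <- match(rkey, residue_key(res$chain_id, res$seq_num, res$ins_code))
    keep <- !is.na(idx)
    at <- data.frame(seq_index = idx[keep] - 1L, atom = ca$atom[keep],
                     x = ca$x[keep], y = ca$y[keep], z = ca$z[keep],
                     stringsAsFactors = FALSE)
    chains[[cid]] <- chain_structure(cid, res, at)
  }
  chains
}
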