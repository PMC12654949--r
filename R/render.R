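# Rendering: layer -> residue maps, PyMOL / Chimera coloring scripts, and
# extended dot-bracket strings with per-layer bracket families.

#' Default color palette
#'
#' White for unpaired residues, gray for the core layer (layer 0, including
#' any non-canonical pairs it holds), then red, blue, green for non-nested
#' layers 1-3; further layers take orange, purple, cyan and the list cycles
#' when exhausted.
#'
#' @param unpaired,core Color names for unpaired residues and the core layer.
#' @param layers Character vector of colors for layers 1, 2, 3, ...
#' @return A list of class `kl_palette`.
#' @export
default_palette <- function(unpaired = "white", core = "gray",
                            layers = c("red", "blue", "green",
                                       "orange", "purple", "cyan")) {
  structure(list(unpaired = unpaired, core = core, layers = layers),
            class = "kl_palette")
}

palette_layer_color <- function(palette, k) {
  # k >= 1: non-nested layer index; cycles when the list is exhausted
  palette$layers[(k - 1L) %% length(palette$layers) + 1L]
}

#' Map layers to residues
#'
#' For each layer, the residues participating in that layer's pairs, sorted
#' by sequence position; residues in no pair are listed under `unpaired`.
#' A residue appearing in several layers (multiplets split across layers)
#' is assigned to its lowest-numbered layer for coloring.
#'
#' @param d A `layer_decomposition`.
#' @return Named list: `layer0`, `layer1`, ... then `unpaired`, each a
#'   residue data frame (rows of `d$index_map`).
#' @export
residues_by_layer <- function(d) {
  stopifnot(inherits(d, "layer_decomposition"))
  im <- d$index_map
  if (max(c(-1L, unlist(d$layers))) >= nrow(im))
    kl_consistency_error("layer index missing from the residue map")
  assigned <- rep(NA_integer_, nrow(im))  # lowest layer per residue
  for (k in seq_along(d$layers)) {
    idx <- unique(as.vector(d$layers[[k]])) + 1L
    take <- idx[is.na(assigned[idx])]
    assigned[take] <- k - 1L
  }
  out <- list()
  for (k in seq_along(d$layers)) {
    rows <- which(assigned == k - 1L)
    out[[paste0("layer", k - 1L)]] <- im[rows, , drop = FALSE]
  }
  out$unpaired <- im[is.na(assigned), , drop = FALSE]
  out
}

# Author-number token: insertion code appended ("15A").
residue_tokens <- function(res) paste0(res$seq_num, res$ins_code)

#' Emit a PyMOL coloring script
#'
#' Lines, in order: an optional precolor line painting the whole object in
#' the unpaired color (the workflow used for publication figures paints the
#' molecule white first); one `color` line per non-empty layer (core gray,
#' then the layer palette); one `select` line per non-empty non-nested layer
#' so each pseudoknot layer is its own named selection
#' (`<object>_PK_layer<k>`). Residue tokens are author numbers with
#' insertion codes appended.
#'
#' @param d A `layer_decomposition`.
#' @param object_name PyMOL object name.
#' @param chain_id Chain identifier used in the selections.
#' @param palette A [default_palette()]-style palette.
#' @param precolor Paint the whole object in the unpaired color first.
#' @return A list of class `color_script` with `dialect`, `lines`,
#'   `target_object`, `chain_id`.
#' @export
emit_pymol <- function(d, object_name = "rna", chain_id = NULL,
                       palette = default_palette(), precolor = TRUE) {
  stopifnot(inherits(d, "layer_decomposition"))
  chain_id <- chain_id %||% d$index_map$chain_id[1]
  if (is.null(chain_id) || is.na(chain_id) || nrow(d$index_map) == 0L)
    kl_input_error("cannot emit script for an empty chain")
  by_layer <- residues_by_layer(d)
  lines <- character(0)
  if (precolor)
    lines <- c(lines, sprintf("color %s, %s", palette$unpaired, object_name))
  nl <- length(d$layers)
  for (k in seq_len(nl)) {
    res <- by_layer[[paste0("layer", k - 1L)]]
    if (nrow(res) == 0L) next
    col <- if (k == 1L) palette$core else palette_layer_color(palette, k - 1L)
    lines <- c(lines, sprintf("color %s, %s and chain %s and resi %s",
                              col, object_name, chain_id,
                              paste(residue_tokens(res), collapse = "+")))
  }
  for (k in seq_len(max(0L, nl - 1L))) {
    res <- by_layer[[paste0("layer", k)]]
    if (nrow(res) == 0L) next
    lines <- c(lines, sprintf("select %s_PK_layer%d, %s and chain %s and resi %s",
                              object_name, k, object_name, chain_id,
                              paste(residue_tokens(res), collapse = "+")))
  }
  structure(list(dialect = "pymol", lines = lines,
                 target_object = object_name, chain_id = chain_id),
            class = "color_script")
}

#' Emit a Chimera coloring script
#'
#' Classic Chimera 1.x command dialect:
#' `color <color> #<model>:<n1>,<n2>,....<chain>`; no selection lines
#' (named per-layer selections are a PyMOL-side feature).
#'
#' @param d A `layer_decomposition`.
#' @param model_id Chimera model number.
#' @inheritParams emit_pymol
#' @return A `color_script` (dialect `"chimera"`).
#' @export
emit_chimera <- function(d, model_id = 0, chain_id = NULL,
                         palette = default_palette(), precolor = TRUE) {
  stopifnot(inherits(d, "layer_decomposition"))
  chain_id <- chain_id %||% d$index_map$chain_id[1]
  if (is.null(chain_id) || is.na(chain_id) || nrow(d$index_map) == 0L)
    kl_input_error("cannot emit script for an empty chain")
  by_layer <- residues_by_layer(d)
  lines <- character(0)
  if (precolor)
    lines <- c(lines, sprintf("color %s #%s", palette$unpaired, model_id))
  for (k in seq_along(d$layers)) {
    res <- by_layer[[paste0("layer", k - 1L)]]
    if (nrow(res) == 0L) next
    col <- if (k == 1L) palette$core else palette_layer_color(palette, k - 1L)
    lines <- c(lines, sprintf("color %s #%s:%s.%s", col, model_id,
                              paste(residue_tokens(res), collapse = ","),
                              chain_id))
  }
  structure(list(dialect = "chimera", lines = lines,
                 target_object = as.character(model_id), chain_id = chain_id),
            class = "color_script")
}

#' @export
print.color_script <- function(x, ...) {
  cat(sprintf("<color_script> dialect %s, target %s, chain %s\n",
              x$dialect, x$target_object, x$chain_id))
  cat(x$lines, sep = "\n")
  invisible(x)
}

# Bracket families: layer 0..3 use ()[]{}<>, layers >= 4 use Aa, Bb, ...
BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

#' Extended dot-bracket string
#'
#' Linear encoding of the decomposition: layer 0 rendered with `()`,
#' layer 1 with `[]`, layer 2 with `{}`, layer 3 with `<>`, deeper layers
#' with uppercase/lowercase letter families (`Aa`, `Bb`, ...); unpaired
#' positions are `.`. A residue pairing in more than one layer cannot be
#' encoded in a single string and raises an error.
#'
#' @param d A `layer_decomposition`.
#' @param n String length; defaults to the decomposition's sequence length
#'   and must cover the largest index.
#' @return Single string of length `n`.
#' @export
to_dotbracket <- function(d, n = NULL) {
  stopifnot(inherits(d, "layer_decomposition"))
  n <- as.integer(n %||% d$n)
  if (length(d$layers) > length(BRACKET_OPEN))
    kl_consistency_error(sprintf("more than %d layers unsupported in dot-bracket output",
                                 length(BRACKET_OPEN)))
  idx_used <- unlist(d$layers)
  if (length(idx_used) > 0L && max(idx_used) >= n)
    kl_consistency_error("dot-bracket length smaller than largest pair index")
  chars <- rep(".", n)
  for (k in seq_along(d$layers)) {
    lay <- d$layers[[k]]
    if (nrow(lay) == 0L) next
    pos <- as.vector(lay) + 1L
    if (any(chars[pos] != "."))
      kl_consistency_error("residue pairs in multiple layers; cannot encode as one dot-bracket string")
    chars[lay[, 1] + 1L] <- BRACKET_OPEN[k]
    chars[lay[, 2] + 1L] <- BRACKET_CLOSE[k]
  }
  paste(chars, collapse = "")
}

#' Parse an extended dot-bracket string
#'
#' Inverse of [to_dotbracket()]: recovers the per-family pair sets using one
#' stack per bracket family. Useful for round-trip checks.
#'
#' @param s Dot-bracket string.
#' @return List of 0-based index matrices, one per bracket family present
#'   (family order, empty families before the last used one included).
#' @export
parse_dotbracket <- function(s) {
  chars <- strsplit(s, "")[[1]]
  nf <- length(BRACKET_OPEN)
  stacks <- rep(list(integer(0)), nf)
  out <- rep(list(matrix(integer(0), ncol = 2)), nf)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == ".") next
    k <- match(ch, BRACKET_OPEN)
    if (!is.na(k)) { stacks[[k]] <- c(stacks[[k]], pos - 1L); next }
    k <- match(ch, BRACKET_CLOSE)
    if (is.na(k)) kl_format_error(sprintf("unknown dot-bracket character '%s'", ch))
    if (length(stacks[[k]]) == 0L)
      kl_format_error(sprintf("unbalanced '%s' at position %d", ch, pos))
    i <- stacks[[k]][length(stacks[[k]])]
    stacks[[k]] <- stacks[[k]][-length(stacks[[k]])]
    out[[k]] <- rbind(out[[k]], c(i, pos - 1L))
  }
  if (any(lengths(stacks) > 0L)) kl_format_error("unbalanced dot-bracket string")
  used <- which(vapply(out, nrow, integer(1)) > 0L)
  if (length(used) == 0L) return(list())
  out <- out[seq_len(max(used))]
  lapply(out, function(mm) mm[order(mm[, 1]), , drop = FALSE])
}
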