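# Corpus-level summaries: per-chain layer records, layer-count histogram,
# and per-layer non-canonical fraction (the shape of a corpus-scale survey
# of pseudoknot layers).

#' Summarize one chain's decomposition
#'
#' Per-layer canonical / non-canonical pair counts for one decomposed chain.
#' Chains with zero pairs yield an excluded record (corpus statistics drop
#' entries with no base pairs / layers).
#'
#' @param d A `layer_decomposition` (carries per-pair canonical flags).
#' @param chain_label Label used in corpus tables.
#' @return A list of class `chain_record`: `chain_label`, `mode`,
#'   `layer_sizes`, `canonical_counts`, `noncanonical_counts`, `excluded`.
#' @export
summarize_chain <- function(d, chain_label = "chain") {
  stopifnot(inherits(d, "layer_decomposition"))
  if (length(d$canonical) != nrow(d$pairs))
    kl_consistency_error("canonical flags do not match the decomposition's pairs")
  nl <- length(d$layers)
  if (nl == 0L) {
    return(structure(list(chain_label = chain_label, mode = d$mode,
                          layer_sizes = integer(0),
                          canonical_counts = integer(0),
                          noncanonical_counts = integer(0), excluded = TRUE),
                     class = "chain_record"))
  }
  can <- integer(nl); non <- integer(nl)
  for (k in seq_len(nl)) {
    in_k <- d$layer_id == k - 1L
    can[k] <- sum(d$canonical[in_k])
    non[k] <- sum(!d$canonical[in_k])
  }
  sizes <- layer_sizes(d)
  if (any(can + non != sizes))
    kl_consistency_error("per-layer counts do not sum to layer sizes")
  structure(list(chain_label = chain_label, mode = d$mode, layer_sizes = sizes,
                 canonical_counts = can, noncanonical_counts = non,
                 excluded = FALSE),
            class = "chain_record")
}

included_records <- function(records) {
  Filter(function(r) !r$excluded, records)
}

#' Layer-count histogram over a corpus
#'
#' Distribution of the number of layers per chain (excluded records dropped),
#' plus the cumulative fraction of chains with at most k layers.
#'
#' @param records List of `chain_record`s.
#' @return Data frame with columns `layer_count`, `n_chains`, `fraction`,
#'   `cum_fraction`.
#' @export
layer_histogram <- function(records) {
  inc <- included_records(records)
  if (length(inc) == 0L)
    kl_empty_error("no chains remain after excluding zero-pair entries")
  counts <- vapply(inc, function(r) length(r$layer_sizes), integer(1))
  tab <- table(factor(counts, levels = seq_len(max(counts))))
  df <- data.frame(layer_count = as.integer(names(tab)),
                   n_chains = as.integer(tab))
  df$fraction <- df$n_chains / sum(df$n_chains)
  df$cum_fraction <- cumsum(df$fraction)
  df
}

#' Per-layer non-canonical fraction
#'
#' For each layer index, the mean over chains (possessing that layer) of the
#' chain's non-canonical fraction in that layer, alongside the pooled-count
#' fraction. Requires include_all records: under canonical_only every
#' non-canonical count is zero by construction and the fraction is
#' meaningless.
#'
#' @param records List of `chain_record`s produced in `include_all` mode.
#' @return Data frame with columns `layer`, `mean_noncanonical_fraction`,
#'   `pooled_noncanonical_fraction`, `n_chains`.
#' @export
canonical_fraction_by_layer <- function(records) {
  inc <- included_records(records)
  if (length(inc) == 0L)
    kl_empty_error("no chains remain after excluding zero-pair entries")
  if (any(vapply(inc, function(r) r$mode, "") != "include_all"))
    kl_consistency_error("canonical_fraction_by_layer requires include_all records")
  max_l <- max(vapply(inc, function(r) length(r$layer_sizes), integer(1)))
  rows <- lapply(seq_len(max_l), function(k) {
    have <- Filter(function(r) length(r$layer_sizes) >= k, inc)
    fr <- vapply(have, function(r)
      r$noncanonical_counts[k] / r$layer_sizes[k], numeric(1))
    non <- sum(vapply(have, function(r) r$noncanonical_counts[k], integer(1)))
    tot <- sum(vapply(have, function(r) r$layer_sizes[k], integer(1)))
    data.frame(layer = k - 1L, mean_noncanonical_fraction = mean(fr),
               pooled_noncanonical_fraction = non / tot,
               n_chains = length(have))
  })
  do.call(rbind, rows)
}
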