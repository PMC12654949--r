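# Internal helpers: structured error conditions, residue keys, small shared
# utilities. Error classes map to the CLI's stable exit codes (see pkv_cli).

kl_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "kl_error")))
}

kl_input_error <- function(msg) kl_stop(msg, "kl_input_error")
kl_format_error <- function(msg) kl_stop(msg, "kl_format_error")
kl_consistency_error <- function(msg) kl_stop(msg, "kl_consistency_error")
kl_empty_error <- function(msg) kl_stop(msg, "kl_empty_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# One residue identity key per row of a residue table (chain/number/insertion).
residue_key <- function(chain_id, seq_num, ins_code) {
  paste(chain_id, seq_num, ifelse(is.na(ins_code) | ins_code == "", "_", ins_code),
        sep = ":")
}

# Warn once per distinct label within a session (e.g. unknown geometry classes).
.kl_env <- new.env(parent = emptyenv())

warn_once <- function(key, msg) {
  seen <- get0("seen_labels", envir = .kl_env, ifnotfound = character(0))
  if (!key %in% seen) {
    assign("seen_labels", c(seen, key), envir = .kl_env)
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

empty_residue_df <- function() {
  data.frame(chain_id = character(0), seq_num = integer(0),
             ins_code = character(0), res_name = character(0),
             seq_index = integer(0), stringsAsFactors = FALSE)
}

empty_pair_df <- function() {
  data.frame(chain1 = character(0), seq1 = integer(0), ins1 = character(0),
             name1 = character(0), chain2 = character(0), seq2 = integer(0),
             ins2 = character(0), name2 = character(0),
             geometry_class = character(0), canonical = logical(0),
             source = character(0), stringsAsFactors = FALSE)
}

# Normalize a pair data frame so res1 precedes res2 in (chain, number,
# insertion) order; drops self-pairs with a warning.
normalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  k1 <- residue_key(pairs$chain1, pairs$seq1, pairs$ins1)
  k2 <- residue_key(pairs$chain2, pairs$seq2, pairs$ins2)
  self <- k1 == k2
  if (any(self)) {
    warning(sprintf("dropping %d self-pair(s)", sum(self)), call. = FALSE)
    pairs <- pairs[!self, , drop = FALSE]
    k1 <- k1[!self]; k2 <- k2[!self]
  }
  if (nrow(pairs) == 0L) return(pairs)
  o1 <- order(pairs$chain1, pairs$seq1, pairs$ins1)
  # res1 precedes res2 when (chain, num, ins) sorts first
  swap <- mapply(function(c1, n1, i1, c2, n2, i2) {
    if (c1 != c2) return(c1 > c2)
    if (n1 != n2) return(n1 > n2)
    i1 > i2
  }, pairs$chain1, pairs$seq1, pairs$ins1,
     pairs$chain2, pairs$seq2, pairs$ins2, USE.NAMES = FALSE)
  if (any(swap)) {
    tmp <- pairs[swap, c("chain1", "seq1", "ins1", "name1")]
    pairs[swap, c("chain1", "seq1", "ins1", "name1")] <-
      pairs[swap, c("chain2", "seq2", "ins2", "name2")]
    pairs[swap, c("chain2", "seq2", "ins2", "name2")] <- tmp
  }
  rownames(pairs) <- NULL
  pairs
}
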