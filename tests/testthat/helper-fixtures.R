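# Shared fixtures built in code.

# H-type pseudoknot used throughout: stems of 3 and 2 mutually crossing
# pairs on 20 residues. Ground truth: the two stems conflict pairwise, so
# the maximum non-crossing subset is the size-3 stem and the greedy
# decomposition is [3, 2] (confirmed against the exhaustive oracle in
# test-layering.R).
htype_pairs <- function() {
  rbind(c(0L, 9L), c(1L, 8L), c(2L, 7L), c(4L, 13L), c(5L, 12L))
}
htype_n <- 20L

htype_decomposition <- function() {
  decompose_layers(indexed_pair_set(htype_pairs(), n = htype_n))
}

# Non-minimality witness: the unique maximum non-crossing subset mixes the
# two optimal layers, so greedy needs 3 layers where 2 suffice
# (2-layerability is proved by the bipartiteness oracle in the tests).
witness_pairs <- function() {
  rbind(c(0L, 5L), c(1L, 4L), c(12L, 21L), c(10L, 17L), c(11L, 16L), c(2L, 20L))
}
witness_n <- 22L

# residue tokens referenced by a script's color lines (the precolor line
# carries none); used to compare dialects
script_residues <- function(script) {
  toks <- regmatches(script$lines,
                     regexpr("(resi [0-9A-Za-z+]+|:[0-9A-Za-z,]+)", script$lines))
  sort(unique(unlist(strsplit(gsub("^resi |^:", "", toks), "[+,]"))))
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "knotlayer")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", name)
  p
}
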