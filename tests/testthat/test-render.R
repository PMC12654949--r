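# Rendering: residue maps, PyMOL/Chimera scripts, dot-bracket round trips.

test_that("residues_by_layer partitions the chain with the lowest-layer rule", {
  d <- htype_decomposition()
  by <- residues_by_layer(d)
  expect_named(by, c("layer0", "layer1", "unpaired"))
  expect_equal(by$layer0$seq_num, c(1L, 2L, 3L, 8L, 9L, 10L))
  expect_equal(by$layer1$seq_num, c(5L, 6L, 13L, 14L))
  expect_equal(nrow(by$unpaired), 10L)
  # exact partition of the chain
  expect_setequal(c(by$layer0$seq_num, by$layer1$seq_num, by$unpaired$seq_num), 1:20)

  # multiplet: residue 7 (index 6) pairs in layer0 and layer1 -> colored layer0
  pairs <- rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L), c(6L, 12L))
  dm <- decompose_layers(indexed_pair_set(pairs, n = 14L))
  expect_equal(layer_count(dm), 2L)
  bym <- residues_by_layer(dm)
  expect_true(7L %in% bym$layer0$seq_num)
  expect_false(7L %in% bym$layer1$seq_num)

  # empty decomposition: everything unpaired
  d0 <- decompose_layers(indexed_pair_set(matrix(integer(0), ncol = 2), n = 4L))
  expect_equal(nrow(residues_by_layer(d0)$unpaired), 4L)
})

test_that("emit_pymol follows the stated emission rules", {
  d <- htype_decomposition()
  s <- emit_pymol(d, object_name = "demo", chain_id = "A", precolor = TRUE)
  expect_s3_class(s, "color_script")
  expect_equal(s$lines, c(
    "color white, demo",
    "color gray, demo and chain A and resi 1+2+3+8+9+10",
    "color red, demo and chain A and resi 5+6+13+14",
    "select demo_PK_layer1, demo and chain A and resi 5+6+13+14"))
  expect_equal(length(s$lines), 4L)

  # precolor=FALSE drops the whole-object line
  s2 <- emit_pymol(d, "demo", "A", precolor = FALSE)
  expect_false(any(grepl("color white, demo$", s2$lines)))
  expect_equal(length(s2$lines), 3L)

  # layer colors red, blue, green in order for a 3-pseudoknot-layer case
  inst <- gen_planted_pairs(c(5, 4, 3, 2), seed = 2)
  d4 <- decompose_layers(planted_ips(inst))
  s4 <- emit_pymol(d4, "x", "A")
  cols <- sub("^color (\\w+),.*$", "\\1", grep("^color", s4$lines, value = TRUE))
  expect_equal(cols, c("white", "gray", "red", "blue", "green"))
})

test_that("emit_chimera uses the classic dialect and matches pymol residue sets", {
  d <- htype_decomposition()
  s <- emit_chimera(d, model_id = 0, chain_id = "A")
  expect_true("color gray #0:1,2,3,8,9,10.A" %in% s$lines)
  expect_false(any(grepl("select", s$lines)))

  p <- emit_pymol(d, "demo", "A")
  expect_equal(script_residues(s), script_residues(p))

  # empty decomposition: only the precolor line
  d0 <- decompose_layers(indexed_pair_set(matrix(integer(0), ncol = 2), n = 4L))
  s0 <- emit_chimera(d0, 0, "A")
  expect_equal(s0$lines, "color white #0")
})

test_that("insertion-coded residues keep their code in tokens", {
  res <- data.frame(chain_id = "A", seq_num = c(14L, 15L, 15L, 16L, 17L, 18L),
                    ins_code = c("", "", "A", "", "", ""),
                    res_name = c("G", "G", "C", "U", "C", "C"),
                    seq_index = 0:5)
  pr <- data.frame(chain1 = "A", seq1 = c(14L, 15L), ins1 = c("", "A"),
                   name1 = c("G", "C"), chain2 = "A", seq2 = c(18L, 17L),
                   ins2 = c("", ""), name2 = c("C", "C"),
                   geometry_class = "WC", canonical = TRUE, source = "DSSR")
  d <- decompose_layers(indexed_pair_set(pr, residues = res))
  s <- emit_pymol(d, "obj", "A")
  expect_true(any(grepl("15A", s$lines)))
  sc <- emit_chimera(d, 0, "A")
  expect_true(any(grepl("15A", sc$lines)))
})

test_that("color completeness: every residue gets exactly one color with precolor", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(10:30, 1L)
    pairs <- rand_pairs(n, max_pairs = 10L)
    d <- decompose_layers(indexed_pair_set(pairs, n = n))
    by <- residues_by_layer(d)
    all_res <- do.call(rbind, by)
    expect_equal(sort(all_res$seq_index), 0:(n - 1L))  # each exactly once
  }
})

test_that("to_dotbracket renders the worked examples", {
  expect_equal(to_dotbracket(htype_decomposition()), "(((.[[.)))..]]......")
  d0 <- decompose_layers(indexed_pair_set(matrix(integer(0), ncol = 2), n = 5L))
  expect_equal(to_dotbracket(d0), ".....")
  nested <- decompose_layers(indexed_pair_set(rbind(c(0L, 9L), c(2L, 5L)), n = 10L))
  expect_true(grepl("^[().]+$", to_dotbracket(nested)))
  # n must cover the largest index
  expect_error(to_dotbracket(htype_decomposition(), n = 10L),
               class = "kl_consistency_error")
})

test_that("deep layers use letter bracket families", {
  inst <- gen_planted_pairs(c(6, 5, 4, 3, 2, 1), seed = 0)
  d <- decompose_layers(planted_ips(inst))
  expect_equal(layer_count(d), 6L)
  db <- to_dotbracket(d)
  expect_true(grepl("A", db) && grepl("a", db))
  expect_true(grepl("B", db) && grepl("b", db))
  back <- parse_dotbracket(db)
  expect_equal(length(back), 6L)
})

test_that("dot-bracket round-trip recovers the layer partition", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(8:30, 1L)
    pairs <- rand_pairs(n, max_pairs = 12L, share_endpoints = FALSE)
    d <- decompose_layers(indexed_pair_set(pairs, n = n))
    back <- parse_dotbracket(to_dotbracket(d))
    expect_equal(length(back), layer_count(d))
    for (k in seq_along(back))
      expect_equal(back[[k]], d$layers[[k]], ignore_attr = TRUE)
  }
  # a multiplet split across layers cannot be encoded
  pairs <- rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L), c(6L, 12L))
  dm <- decompose_layers(indexed_pair_set(pairs, n = 14L))
  expect_error(to_dotbracket(dm), class = "kl_consistency_error")
})

test_that("palette cycles beyond its list", {
  pal <- default_palette(layers = c("red", "blue"))
  expect_equal(knotlayer:::palette_layer_color(pal, 3L), "red")
  expect_equal(knotlayer:::palette_layer_color(pal, 4L), "blue")
})
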