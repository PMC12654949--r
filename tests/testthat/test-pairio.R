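# Structure readers, annotator parsers, canonical classification, selection.

test_that("read_structure round-trips the mmCIF fixture and matches PDB output", {
  h <- gen_planted_pairs(c(3, 2), seed = 0)
  cif <- withr::local_tempfile(fileext = ".cif")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  gen_helix_mmcif(h, cif)
  gen_helix_structure(h, pdb, format = "pdb")

  ch_cif <- read_structure(cif)
  expect_named(ch_cif, "A")
  expect_equal(nrow(ch_cif$A$residues), 20L)
  expect_equal(ch_cif$A$residues$seq_index, 0:19)
  expect_equal(ch_cif$A$residues$seq_num, 1:20)
  expect_equal(ch_cif$A$residues$res_name, h$res_names)

  # cross-format equality: same chain/residue list from the PDB rendering
  ch_pdb <- read_structure(pdb)
  expect_equal(ch_pdb$A$residues, ch_cif$A$residues)
  expect_equal(ch_pdb$A$atoms$atom, ch_cif$A$atoms$atom)
  expect_equal(ch_pdb$A$atoms$x, ch_cif$A$atoms$x, tolerance = 1e-6)
})

test_that("read_structure rejects missing files, protein-only and garbage input", {
  expect_error(read_structure("/nonexistent/file.pdb"), class = "kl_input_error")
  protein <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CB  ALA A   2       1.000   0.000   0.000  1.00  0.00",
    "END"), protein)
  expect_error(read_structure(protein), class = "kl_empty_error")
  junk <- withr::local_tempfile(fileext = ".pdb")
  writeLines("no atoms here", junk)
  expect_error(read_structure(junk), class = "kl_format_error")
})

test_that("altloc duplicates collapse to the first conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(id, name, alt, x)
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            id, name, alt, "G", "A", 1L, x, 0, 0)
  writeLines(c(atom_line(1L, " C1'", "A", 0),
               atom_line(2L, " C1'", "B", 9.999),
               atom_line(3L, " N1", "A", 1),
               "END"), f)
  ch <- read_structure(f)
  expect_equal(nrow(ch$A$residues), 1L)
  a <- ch$A$atoms
  expect_equal(a$x[a$atom == "C1'"], 0)
})

test_that("parse_rnaview handles the packaged fixture, stacked lines and errors", {
  p <- parse_rnaview(readLines(fixture_path("example_rnaview.out")))
  expect_equal(nrow(p), 4L)  # stacked line skipped
  expect_equal(sum(p$canonical), 3L)
  expect_equal(p$geometry_class, c("+/+ cis", "+/+ cis", "W/W cis", "H/W tran"))
  expect_true(all(p$source == "RNAView"))
  # res1 precedes res2 after normalization
  expect_true(all(p$seq1 < p$seq2))
  expect_error(parse_rnaview(""), class = "kl_format_error")
  expect_error(parse_rnaview("some random\ntext lines"), class = "kl_format_error")
})

test_that("parse_rnaview keeps inter-chain pairs for later filtering", {
  txt <- c("     1_30, A:     1 G-C    30 B: +/+ cis         XIX",
           "     2_29, A:     2 A-U    29 A: +/+ cis         XX")
  p <- parse_rnaview(txt)
  expect_equal(nrow(p), 2L)
  expect_equal(sum(p$chain1 != p$chain2), 1L)
  sel <- suppressWarnings(select_pairs(p, "A", "include_all"))
  expect_equal(nrow(sel), 1L)
})

test_that("parse_dssr handles the packaged fixture, ins codes and errors", {
  p <- parse_dssr(readLines(fixture_path("example_dssr.json")))
  expect_equal(nrow(p), 3L)
  expect_equal(sum(p$canonical), 2L)
  expect_equal(p$geometry_class, c("WC", "Wobble", "Hoogsteen"))

  expect_equal(nrow(parse_dssr('{"pairs": []}')), 0L)
  expect_error(parse_dssr("{not json"), class = "kl_format_error")

  ins <- parse_dssr('{"pairs": [{"nt1": "A.G15^B", "nt2": "A.C40", "name": "WC"}]}')
  expect_equal(ins$ins1, "B")
  expect_equal(ins$seq1, 15L)
  expect_equal(ins$name1, "G")

  # modified nucleotide id: trailing digits are the number
  mod <- parse_dssr('{"pairs": [{"nt1": "A.5MU54", "nt2": "A.A58", "name": "rHoogsteen"}]}')
  expect_equal(mod$name1, "5MU")
  expect_equal(mod$seq1, 54L)
  expect_false(mod$canonical)

  expect_warning(
    p2 <- parse_dssr('{"pairs": [{"nt1": "A.G1", "name": "WC"},
                                 {"nt1": "A.G2", "nt2": "A.C9", "name": "WC"}]}'),
    "missing")
  expect_equal(nrow(p2), 1L)
})

test_that("classify_canonical implements identity x cis-WC geometry", {
  expect_true(classify_canonical("G", "C", "WC", "DSSR"))
  expect_true(classify_canonical("G", "U", "Wobble", "DSSR"))
  expect_false(classify_canonical("A", "G", "H/W tran", "RNAView"))
  expect_false(classify_canonical("G", "C", "Hoogsteen", "DSSR"))
  expect_true(classify_canonical("A", "U", "+/+ cis", "RNAView"))
  expect_true(classify_canonical("G", "U", "W/W cis", "RNAView"))
  expect_false(classify_canonical("G", "U", "W/W tran", "RNAView"))
  expect_true(classify_canonical("G", "C", "builtin", "builtin"))
  # identity-only switch
  expect_true(classify_canonical("G", "C", "Hoogsteen", "DSSR",
                                 require_cis_wc = FALSE))
  # modified nucleotides map to parents; unmapped codes are never canonical
  expect_true(classify_canonical("5MC", "G", "WC", "DSSR"))
  expect_false(classify_canonical("XYZ", "G", "WC", "DSSR"))
})

test_that("classify_canonical is symmetric in residue identities", {
  combos <- expand.grid(a = c("A", "C", "G", "U"), b = c("A", "C", "G", "U"),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    expect_equal(
      classify_canonical(combos$a[r], combos$b[r], "WC", "DSSR"),
      classify_canonical(combos$b[r], combos$a[r], "WC", "DSSR"))
  }
})

test_that("builtin detector recovers planted pairs and respects geometry windows", {
  h <- gen_planted_pairs(c(3, 2), seed = 0)
  cif <- withr::local_tempfile(fileext = ".cif")
  gen_helix_mmcif(h, cif)
  ch <- read_structure(cif)$A
  p <- detect_pairs_builtin(ch)
  expect_equal(nrow(p), 5L)
  got <- cbind(p$seq1 - 1L, p$seq2 - 1L)
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(h$pairs[, 1], h$pairs[, 2]))
  expect_true(all(p$canonical))
  expect_true(all(p$geometry_class == "builtin"))

  # translating one strand far out of range kills all pairs
  ch2 <- ch
  right <- ch2$residues$seq_index[ch2$residues$seq_index >= 7]
  move <- ch2$atoms$seq_index %in% right
  ch2$atoms$z[move] <- ch2$atoms$z[move] + 5
  expect_equal(nrow(detect_pairs_builtin(ch2)), 0L)
})

test_that("builtin detector skips residues missing required atoms", {
  h <- gen_planted_pairs(c(2, 1), seed = 3)
  cif <- withr::local_tempfile(fileext = ".cif")
  gen_helix_mmcif(h, cif)
  ch <- read_structure(cif)$A
  # drop the WC-edge nitrogen of the first planted residue
  first <- h$pairs[1, 1]
  drop <- ch$atoms$seq_index == first & ch$atoms$atom != "C1'"
  ch$atoms <- ch$atoms[!drop, , drop = FALSE]
  expect_warning(p <- detect_pairs_builtin(ch), "skipped")
  expect_equal(nrow(p), nrow(h$pairs) - 1L)
})

test_that("select_pairs filters chain, mode and duplicates", {
  pairs <- parse_rnaview(c(
    "     1_20, A:     1 G-C    20 A: +/+ cis         XIX",
    "     2_19, A:     2 A-U    19 A: +/+ cis         XX",
    "     3_18, A:     3 G-U    18 A: W/W cis         XXVIII",
    "     4_17, A:     4 A-G    17 A: H/W tran        !1H(b_b)",
    "     5_40, A:     5 G-C    40 B: +/+ cis         XIX"))
  expect_equal(nrow(select_pairs(pairs, "A", "canonical_only")), 3L)
  expect_equal(nrow(select_pairs(pairs, "A", "include_all")), 4L)
  expect_warning(none <- select_pairs(pairs, "Z", "include_all"), "absent")
  expect_equal(nrow(none), 0L)

  # canonical_only subset of include_all
  ca <- select_pairs(pairs, "A", "canonical_only")
  ia <- select_pairs(pairs, "A", "include_all")
  key <- function(x) paste(x$seq1, x$seq2)
  expect_true(all(key(ca) %in% key(ia)))

  # duplicate annotations collapse, canonical wins
  dup <- pairs[c(1, 1), ]
  dup$canonical[2] <- FALSE
  dup$geometry_class[2] <- "H/W tran"
  got <- select_pairs(dup, "A", "include_all")
  expect_equal(nrow(got), 1L)
  expect_true(got$canonical)
})

test_that("parser idempotence: rendering and re-parsing preserves the pair multiset", {
  h <- gen_planted_pairs(c(3, 2), seed = 5, noncanonical_fraction = 0.4)
  rv <- withr::local_tempfile(fileext = ".out")
  dj <- withr::local_tempfile(fileext = ".json")
  gen_rnaview_file(h, rv)
  gen_dssr_file(h, dj)
  for (p in list(parse_rnaview(readLines(rv)), parse_dssr(readLines(dj)))) {
    expect_equal(nrow(p), nrow(h$pairs))
    expect_setequal(paste(p$seq1 - 1L, p$seq2 - 1L),
                    paste(h$pairs[, 1], h$pairs[, 2]))
    expect_equal(sum(p$canonical), sum(h$canonical))
  }
})
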