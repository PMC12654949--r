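# knotlayer

Pseudoknot layer decomposition and viewer coloring scripts for RNA 3D
structures.

RNA pseudoknots — base pairs that *cross* other pairs when the structure is
drawn on a line — are hard to spot by eye in a tertiary structure,
especially for chains of hundreds of nucleotides. Any base-pair set can be
partitioned into *pseudoknot-free layers*: `knotlayer` extracts a chain's
base pairs, decomposes them into such layers, and emits PyMOL or Chimera
commands that color each layer differently (white unpaired, gray core,
red/blue/green for non-nested layers 1–3), plus extended dot-bracket
strings and corpus-level layer statistics. It is aimed at structural RNA
researchers inspecting experimental or predicted tertiary structures.

## The algorithm

Pairs of one chain are mapped to 0-based sequential indices. Pairs
$(i,j)$ and $(k,l)$ cross iff $i<k<j<l$ or $k<i<l<j$. Each layer is a
maximum-cardinality non-crossing, one-pair-per-index subset of the
remaining pairs, found by a Nussinov-style interval DP
($O(n^3)$ time / $O(n^2)$ space per pass):

    M[i,j] = max( M[i+1,j],
                  max over pairs (i,k), i < k <= j of
                      M[i+1,k-1] + M[k+1,j] + 1 )

Extraction repeats until no pairs remain. Layer 0 (core) is the largest;
the *pseudoknot order* is the number of layers beyond it. The greedy
scheme maximizes the core (so pseudoknot layers stay small and visible)
and does **not** guarantee the minimum number of layers — the test suite
contains a verified witness where greedy uses 3 layers and 2 suffice.

Base pairs come from pre-computed annotator output (RNAView text or DSSR
JSON — the binaries are never run), or from a built-in geometric detector
(canonical identities with WC-edge N···N ≤ 3.2 Å, C1′–C1′ ∈ [9.8, 11.0] Å,
separation > 2). Canonical = {A–U, G–C, G–U} *and* cis-WC geometry; the
`include_all` mode keeps non-canonical pairs (layers are then "non-nested
layers" in the broader sense).

## Worked example

Generate the classic H-type pseudoknot fixture (two mutually crossing
stems of 3 and 2 pairs on 20 residues), write it as mmCIF, and run the
pipeline through the CLI entry point:

```r
library(knotlayer)
h <- gen_planted_pairs(c(3, 2), seed = 0)
gen_helix_mmcif(h, "htype.cif")
pkv_cli(c("-i", "htype.cif", "-o", "htype.pml", "-a", "builtin",
          "-c", "A", "-f", "pymol", "--dotbracket", "htype.db"))
#> annotator=builtin mode=canonical_only chain=A layers=[3,2] pseudoknot_order=1
```

`htype.pml` (paste into the PyMOL command line):

```
color white, htype
color gray, htype and chain A and resi 1+2+3+8+9+10
color red, htype and chain A and resi 5+6+13+14
select htype_PK_layer1, htype and chain A and resi 5+6+13+14
```

Reading: the whole object is pre-colored white (unpaired); residues
1–3/8–10 form the core stem (gray); residues 5–6/13–14 form pseudoknot
layer 1 (red) and get their own named selection. `htype.db` holds the
extended dot-bracket string, one bracket family per layer:

```
> htype chain A
(((.[[.)))..]]......
```

`-f chimera` emits the classic Chimera dialect instead
(`color gray #0:1,2,3,8,9,10.A`). With pre-computed annotations:
`-a RNAView --annotation file.out` or `-a DSSR --annotation file.json`;
`--include-all` keeps non-canonical pairs. Corpus statistics:

```sh
Rscript inst/cli/knotlayer stats --synthetic 100 --seed 1 --include-all --outdir stats/
```

writes `layer_histogram.csv` (layer-count distribution with cumulative
fractions) and `canonical_fraction.csv` (per-layer mean non-canonical
fraction); a manifest of local structures (`path<TAB>chain` per line) can
replace the synthetic corpus via `--manifest`.

Equivalent R-level API: `read_structure()`, `parse_rnaview()` /
`parse_dssr()` / `detect_pairs_builtin()`, `select_pairs()`,
`indexed_pair_set()`, `decompose_layers()`, `emit_pymol()` /
`emit_chimera()` / `to_dotbracket()`, `summarize_chain()` /
`layer_histogram()` / `canonical_fraction_by_layer()`.

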