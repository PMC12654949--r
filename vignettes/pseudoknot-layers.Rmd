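---
title: "Pseudoknot layer decomposition: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoknot layer decomposition: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotlayer)
```

## The problem

A pseudoknot is a base-pairing interaction between a loop and a region
outside its enclosing stem. Drawn on a line, its base pairs *cross* other
pairs: the pair set is not representable as a single planar (nested)
secondary structure. Any pair set can, however, be partitioned into
*pseudoknot-free layers*, each internally non-crossing. Coloring the
residues of each layer differently in a 3D viewer makes the spatial layout
of pseudoknots in a tertiary structure immediately visible, which is
otherwise hard to inspect for chains of hundreds of nucleotides.

`knotlayer` takes a chain's base pairs — parsed from RNAView text output or
DSSR JSON output, or detected geometrically from PDB/mmCIF coordinates by a
built-in fallback — decomposes them into layers, and renders the result as
PyMOL or Chimera coloring commands, as an extended dot-bracket string, and
as corpus-level statistics.

## The decomposition model

Pairs are first mapped to 0-based sequential indices within the chain
(author numbering may contain gaps and insertion codes; the DP never sees
them). Two index pairs $(i,j)$ and $(k,l)$ **cross** iff $i<k<j<l$ or
$k<i<l<j$; sharing an endpoint is a separate conflict, excluded within a
layer by the one-pair-per-index rule rather than by the crossing predicate.

One extraction step finds a **maximum-cardinality non-crossing,
one-pair-per-index subset** of the remaining pairs with a Nussinov-style
interval DP. With $M[i,j]$ the best count using positions $i..j$ and $E$
the allowed pairs:

$$
M[i,j] = \max\Big( M[i{+}1,j],\;
  \max_{(i,k)\in E,\; i<k\le j} M[i{+}1,k{-}1] + M[k{+}1,j] + 1 \Big)
$$

answered by $M[1,n]$; $O(n^3)$ time, $O(n^2)$ space per pass. The selected
subset becomes the next layer and is removed; extraction repeats until no
pairs remain. Layer 0 (the *core*) is the first and largest; subsequent
layers are the non-nested (pseudoknot) layers; the **pseudoknot order** is
the number of layers beyond the core. Greedy maxima are non-increasing in
size, and every pair of layer $k \ge 1$ necessarily conflicts with every
earlier layer (else that earlier maximum was not maximal) — both are tested
as invariants on 1000 random instances.

**The greedy layering is deliberately not minimal.** Maximizing the core
keeps the pseudoknot layers small, which is what one wants to *see*; but
iterated maximum extraction can use more layers than the minimum
achievable. The test suite contains a 6-pair witness whose unique maximum
non-crossing subset mixes the two halves of an optimal 2-layer partition,
forcing a third layer (2-layerability is proved there by exhaustive
2-coloring of the conflict graph). This behaviour is asserted, not "fixed":
minimum-layer decomposition is a non-goal.

**Tie-breaking.** Which maximum subset is extracted is
visualization-irrelevant but must be reproducible: the traceback prefers
pairing position $i$ over leaving it unpaired when scores tie, and among
tied partners chooses the smallest $k$. Two runs on the same input are
bit-identical.

**Safety cap.** Decomposition aborts (consistency error) beyond 26 layers;
real chains rarely exceed 4, so the cap only catches malformed input.

## Canonical pairs

A pair is canonical iff its identity is A–U, G–C, or wobble G–U **and** the
source annotator calls cis Watson–Crick geometry (RNAView `+/+`, `-/-`, or
`W/W cis`; DSSR name `WC` or `Wobble`; the builtin detector only ever
reports canonical pairs). Identity alone does not suffice — a G·C Hoogsteen
pair is universally treated as non-canonical — but the stricter rule is a
design choice here, so `classify_canonical(..., require_cis_wc = FALSE)`
gives the identity-only classification. Modified nucleotides fold to their
parent base through an extensible mapping (`PSU -> U`, `5MC -> C`, ...);
unmapped codes are never canonical. Under the default `canonical_only`
selection mode the layers are pseudoknot layers proper; `include_all`
retains non-canonical pairs and the layers are then non-nested layers in
the broader sense.

## The built-in detector

When neither annotator output is available, pairs are detected from
coordinates: residues $i$, $j$ with $j - i > 2$ in sequential index,
canonical identity combination, Watson–Crick-edge nitrogen distance
(N1 for purines, N3 for pyrimidines) $\le 3.2$ Å, and C1′–C1′ distance in
$[9.8, 11.0]$ Å. These are standard canonical-pair geometry envelopes; the
detector is intentionally blind to non-canonical geometries (a non-goal).
Residues missing the required atoms are skipped with a warning. Alternate
locations collapse to the first-listed conformer; insertion codes
participate in residue identity everywhere.

## Synthetic data: what it emulates and what it does not

`gen_planted_pairs(sizes)` lays out $k$ helical stems as opener blocks
$O_1..O_k$ followed by closer blocks $C_1..C_k$ in the same order, with
1-residue gaps between opener blocks, 2-residue gaps between closer blocks
and a 6-residue unpaired tail. Every pair of one stem then crosses every
pair of every other stem, so the conflict graph is complete multipartite
and the maximum non-crossing subset is exactly the largest stem: for
strictly decreasing sizes the greedy decomposition provably equals the
planted layering (and is additionally cross-checked against a brute-force
subset-enumeration oracle in the tests). For tied sizes only the size
multiset is guaranteed, and the generator flags such instances. Sizes
`c(3, 2)` give the canonical H-type pseudoknot on 20 residues used
throughout the tests.

`gen_corpus(n, seed)` samples per-chain layer counts 1–4 with probabilities
0.55/0.30/0.10/0.05 — concentrated on few layers, echoing the observation
that over 80 % of real chains need at most 2–3 layers — with strictly
decreasing stem sizes drawn without replacement from 2–12, and relabels
pairs non-canonical with probability 0.10 in the core and 0.50 outside it,
planting the empirically observed enrichment of non-canonical pairs in
non-nested layers. These values were fixed once as the generator's stated
world and are not tuned to test outcomes.

The idealized structure writer places each pair's four relevant atoms in an
isolated cluster (C1′–C1′ 10.4 Å, N–N 3.0 Å, clusters 50 Å apart, unpaired
residues far away). This is schematic geometry: it exercises the I/O and
detection *contracts* exactly, but a green end-to-end test establishes
nothing about stereochemically realistic A-form helices, crowded cores, or
borderline geometries near the thresholds. Likewise the synthetic corpus
reproduces planted layer-count distributions, not any real database's
distribution, which additionally depends on annotator versions and database
snapshots — reproducing those corpus numbers is explicitly out of scope.
A pair with sequence separation $\le 2$ cannot be recovered by the detector
(below its separation floor); the structural fixtures all use separations
$\ge 3$.

## Rendering choices

Colors follow the established scheme: white unpaired, gray core (including
its non-canonical pairs), red/blue/green for non-nested layers 1–3; beyond
that the palette continues orange, purple, cyan and cycles. The whole-object
white precolor is exposed as an explicit flag (default on) rather than a
manual viewer step. PyMOL scripts additionally create one named selection
per pseudoknot layer (`<object>_PK_layer<k>`, a naming scheme chosen here);
the Chimera dialect targets classic Chimera 1.x command syntax (ChimeraX is
a non-goal) and has no selection lines. A residue pairing in several layers
(multiplets split by the decomposition) is colored by its lowest layer.

Dot-bracket output assigns fixed bracket families `()`, `[]`, `{}`, `<>`,
then `Aa`, `Bb`, ... per layer. A multiplet residue appearing in two layers
cannot be encoded in one string and raises an error rather than silently
dropping a pair; `parse_dotbracket()` provides the exact inverse used by
the round-trip tests.

## Numerical and degenerate-input choices

* Empty pair set: decomposition has zero layers, pseudoknot order 0, the
  dot-bracket string is all dots, and scripts contain only the optional
  precolor line; such chains are flagged *excluded* in corpus statistics.
* Inter-chain pairs are retained by the parsers and dropped at selection
  time; duplicate annotations of one residue pair collapse with the
  canonical call winning.
* "Per-chain fraction" aggregation in the layer statistics reports both the
  mean of per-chain fractions (default, and what the tests assert) and the
  pooled-count fraction, since the aggregation rule is genuinely open.
* All randomness is seed-controlled; generators save and restore the
  caller's RNG state.

## Limitations

* The annotator binaries are never executed; only their output formats are
  consumed (RNAView pair lines, DSSR `pairs` JSON). Planned-elsewhere
  annotators (MC-Annotate, FR3D, ClaRNA) are out of scope.
* The builtin detector finds canonical pairs only and uses schematic
  distance envelopes, not full Leontis–Westhof edge classification.
* Greedy layering can exceed the minimum layer count (by design, see
  above); no energy- or probability-weighted layer choice is offered.
* Chains supplied only as annotation files have an unknown unpaired residue
  set; scripts then cover paired residues only (a warning says so).
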