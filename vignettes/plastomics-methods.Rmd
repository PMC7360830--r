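---
title: "Methods: comparative plastome analysis with plastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette is the package's own account of its models, conventions and
numerical choices. Nothing here asserts an empirical result that the test
suite does not itself compute.

## The data model

A plastome is a circular molecule; every coordinate in the package is
0-based and half-open on a circular axis, so an interval may wrap the
origin (`interval(start, end, genome_length)` with `start > end`). GenBank
I/O converts to and from 1-based inclusive coordinates only at the file
boundary, which keeps off-by-one arithmetic in exactly one place.
Sequences are uppercased on ingest, `U` becomes `T`, and IUPAC ambiguity
codes other than `N` are mapped to `N` with a warning: the downstream
statistics define behaviour only over `{A,C,G,T,N}`. Trans-spliced genes
(the rps12 convention) are stored as one feature per deposited location
block, linked by shared name; the inventory counts the gene once and sums
its introns over blocks.

## Quadripartite partitioning

`detect_ir()` looks for the maximal pair of disjoint segments `X`, `Y`
with `Y = revcomp(X)`, both at least `min_ir_len` (default 1000 bp),
within `max_mismatch` substitutions (default 0 — congeneric plastomes
have bit-identical IR copies, and an exact default makes every junction
coordinate reproducible). Candidate anti-diagonals come from inverted
20-mer seed matches; each is scanned exhaustively on the circle, flanks
are extended to the first mismatch, and ties between candidate pairs are
broken by total IR length, then smaller start coordinate. The longer
single-copy gap is LSC; IRb is the IR copy downstream of the LSC. With
`max_mismatch > 0` the mirrored-window scan doubles the budget and
re-verifies extracted pairs, which is best-effort rather than provably
maximal; the package's own analyses always run at 0.

Genes straddling a junction are attributed to the region holding the
majority of their length for per-region summaries; `junction_report()`
reports raw overlaps (bp on each side of each junction) and leaves
directional interpretation to the reader.

## Repeat inventories

**SSRs.** Perfect tandem runs of a primitive 1–6 bp unit, with the
conventional survey thresholds (10 copies for mononucleotides, 5, 4, 3,
3, 3 for longer units). A run is reported at its smallest primitive unit
only — an `AT` run is a dinucleotide SSR, never a tetranucleotide
`ATAT`. Motifs are reported forward-strand as they occur, without
reverse-complement canonicalization; on circular molecules the scan
crosses the origin. Runs are truncated to whole copies so
`copies * unit_len = length` holds.

**Dispersed and palindromic repeats.** Four transforms of a segment pair:
forward (identity), reverse, complement, palindromic (reverse
complement), with length ≥ 30, Hamming distance ≤ 3. A reported window
*begins and ends on matching positions* and is maximal among such windows
within the budget. The alternative reading — windows absorbing flanking
mismatches until the budget would be exceeded — makes a planted exact
35-bp pair unreportable at its own length, so the match-bounded
convention is used and is what the brute-force oracle in the tests
verifies. The search seeds on exact k-mers (k from the pigeonhole bound
`(min_len − mm)/(mm + 1)`, capped at 7) and scans padded seed
neighbourhoods; the padding exceeds the maximal distance between seeds
inside any reportable window, so the seeded scan is exhaustive, and the
acceptance suite checks set equality with an unseeded full enumeration.
Self-overlapping pairs are excluded; the two whole-IR copies surface as a
single palindromic record flagged `is_ir`; output is capped at the 100
longest records (ties by coordinates), with the cap and the IR hit both
exposed in summaries because published counts are ambiguous about their
interaction.

**Tandem arrays.** For every period `P ≤ 500`, arrays are located from
runs of the lag-`P` self-match; interruptions of ≤ 3 positions (isolated
substitutions) are bridged, and a candidate must contain a ≥ 10 bp exact
lag-`P` stretch — the "recurring k-mer" seed — without which AT-rich
plastome backgrounds flood the candidate set. Each array is tiled into
`P`-length copies, a majority-rule consensus is formed, and the score is
`+2` per agreeing position and `−7` per disagreement, gaplessly; the
conventional indel penalty (−7) is accepted in the interface but cannot
fire in a gapless tiling. The reported array re-phases itself (start
offset and contiguous copy window maximizing the score), then extends
greedily into a matching partial copy. Scores ≥ 80 with ≥ 2 copies are
reported, and reports of one array at period multiples collapse to the
best-scoring (then shortest) period. This is deliberately not a clone of
wraparound-DP tandem finders: every reported score is hand-checkable.

## Homologous regions, alignment, and the variability statistic

Coding regions are exon-concatenated gene sequences, strand-normalized;
noncoding regions are intergenic spacers named by their ordered flanking
gene pair (`"rpoB-trnC-GCA"`), including the spacer that wraps the
origin. Only regions present under the same name in every genome are
kept; IR-duplicated genes contribute one region taken from the IRb copy.

Alignment is progressive: pairwise guide order by 5-mer Jaccard
similarity, profile–profile Gotoh alignment with affine gaps (match +1,
mismatch −1, open −4, extend −1) in compiled code. The aligner is a
deterministic stand-in for an external MSA tool, and pre-computed aligned
FASTA can be imported verbatim instead (`import_alignment()`).

The variability percentage of an alignment is

\[ \mathrm{percent} = 100\,\frac{S + I}{L_{aln} - L_{indel} + I} \]

with three documented conventions for the multi-sequence case, which the
formula's usual statement leaves open:

* a *gap column* is any column with at least one `-`; `L_indel` counts
  them;
* an *indel event* is one maximal run of gap columns, counted once no
  matter how many taxa are gapped (`I`);
* a *substitution column* (`S`) is a non-gap column with ≥ 2 distinct
  bases among non-`N` residues — site-based, not pairwise, because the
  statistic names "variable sites"; a column with both gaps and base
  differences counts only on the indel side, preventing double counting.

A zero denominator is flagged and reported as 0. Hotspots are the top-7
regions by percent (ties: longer alignment, then name), flagged against
0.5% for within-genus runs and 6% for across-genera runs.

## The dN/dS screen

Nei–Gojobori (1986) counting with the classic conventions: per-codon
synonymous site fractions over the non-stop single-nucleotide changes;
difference counts averaged with equal weight over all mutational pathways
that avoid stop codons; `pX = X_d / X_{sites}` with sites averaged over
the two sequences; Jukes–Cantor correction `−(3/4)·ln(1 − 4p/3)`;
`p ≥ 3/4` flags saturation. The genetic code is the
bacterial/plastid table (stops TAA, TAG, TGA). `selection_screen()`
averages dN and dS over all taxon pairs per gene and flags mean ω > 1.
This is a desk-scale screen: it is *not* expected to reproduce
codon-site-model (Codeml M0–M8, LRT, BEB) results, which operate on a
different inferential basis.

## The marker-discrimination check

p-distances with pairwise deletion of gap/`N` columns over
name-concatenated regions, neighbor joining with deterministic
tie-breaking (smallest sorted cluster-label pair at equal Q) and negative
branch lengths clamped to zero, Robinson–Foulds distances over
non-trivial bipartitions, and a species-exclusivity test: the marker set
discriminates when every species with ≥ 2 individuals appears as a
bipartition of the tree. Single-individual species are vacuously
compatible and reported untestable. NJ is exact on additive matrices,
which the property tests exercise; it replaces external ML/MP/Bayesian
inference because the claim under test is marker discrimination, not a
published topology.

## The simulator: a stated world

`build_ancestor()` emits a quadripartite genome (defaults: 156 kb with a
25.65 kb IR, matching the empirical size regime; the `"test"` preset is a
20 kb / 3 kb miniature used throughout the tests), background GC 36.3%,
with ~23 genes including IR-duplicated copies (mirrored annotations),
intron-containing genes, a junction-straddling gene (120 bp each side of
LSC/IRb), valid ORFs for every CDS, and planted repeats of every class at
recorded coordinates. Guard bases around each plant make it maximal for
its detector, and junction guards prevent chance flank extension of the
IR so structure recovery is exact by construction.

`evolve_along_tree()` walks a newick tree (branch lengths are expected
substitutions per site at multiplier 1): independent site substitutions
at `multiplier(region) × branch length`, uniform among the three
alternative bases; Poisson indel events (rate 0.05 per site per unit
branch length, geometric lengths capped at 10 bp) restricted to
single-copy intergenic spacers; annotations and truth coordinates lifted
through indels; IRb changes mirrored into IRa.

Three simplifications are deliberate and documented: indels never touch
genes or the IR (so homologous-region extraction and IR mirroring remain
well defined — real plastomes do contain coding indels); substitutions
that would create an internal stop codon are reverted (a crude stand-in
for purifying selection that keeps the NG86 pipeline consumable); and
there is no rearrangement, no SSR slippage, and no base-composition
evolution. A green test on this world therefore establishes algorithmic
correctness and parameter recovery, not robustness to annotation errors,
rearrangements or alignment-breaking divergence.

**Why every region gets its own rate multiplier.** The validation target
is a rank correlation between planted rates and measured variability. If
the planted rates took only two values (background 1×, hotspots 10×),
midrank ties would cap the achievable Spearman coefficient near 0.7
regardless of how well the statistic works. The generator therefore
assigns a deterministic log-spaced gradient of multipliers (0.7–3.0) over
regions in genome order, with the three designated hotspot spacers
(`rpoB-trnC-GCA`, `trnT-GGU-psbD`, `psbK-psbI`) overridden to 10×. The
default tree (5 species, 13 individuals, within-species tips 0.002,
stem depths to 0.018) is deep enough that a 300–500 bp region at
multiplier ~1 accumulates tens of variable sites, making neighbouring
gradient ranks resolvable; this places baseline divergence at the upper
(between-genera) end of the empirical range, a choice made for rank
resolution, fixed before any acceptance measurement, and not revisited.

## Numerical and degenerate-input choices

* GC content excludes `N` from numerator and denominator; an all-`N`
  input returns `NA` with a warning.
* `variability_percent` of a zero-denominator alignment is 0 with a flag.
* ω is undefined (NA) when dS = 0 or either rate is saturated; screens
  report such pairs rather than fabricating a ratio.
* All ties anywhere (IR candidates, hotspot ranks, NJ joins, tandem
  period collapse) break deterministically, by length then coordinate or
  name, so identical inputs give identical outputs.
* Seeds: every stochastic entry point takes an explicit integer seed;
  `(config, seed)` determines the simulator's output byte for byte.

## Known limitations

The dispersed-repeat scan is exhaustive but quadratic in repeat-dense
regions; genome-scale inputs with very low complexity are slower than
suffix-tree tools. The aligner is a guide-order progressive method
without iterative refinement and should not be used for distant homologs.
`max_mismatch > 0` IR detection is best-effort. The NG86 screen ignores
transition/transversion bias by design (hand-verifiable pathway
weights). The CLI reads one genome per file.
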