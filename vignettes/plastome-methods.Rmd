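---
title: "Methods: comparative plastome analysis with plastome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastome)
```

This vignette documents the models and procedures implemented in
`plastome`, their assumptions, the tunable parameters, and the numerical
and design choices made where the methodology left room.

## Coordinates and input conventions

All internal coordinates are 0-based half-open. GenBank locations (1-based
inclusive) are converted on read; the marker-table TSV output keeps 0-based
starts, and BED output is standard BED6. Ambiguity codes other than `N` are
mapped to `N` with a warning; the diversity estimator treats `N` exactly
like a gap (not comparable). Features that span the origin of a circular
molecule are kept as single intervals with "unwrapped" ends (`end` may
exceed the genome length) rather than being split: all downstream distance
computations are circular, so unwrapped intervals are the representation
that keeps junction arithmetic simple.

## Quadripartite structure

A plastome is modelled as a circular sequence carrying two identical,
oppositely oriented repeats (IRa, IRb) separating a large and a small
single-copy region. `detect_inverted_repeats()` searches for the maximal
pair of *exact* inverted repeats: the doubled sequence is compared against
its reverse complement through 15-mer seeds extended without mismatches,
per-diagonal bookkeeping keeps the scan near-linear, and candidate pairs
that overlap on the circle or fall below `min_ir_len` are discarded. The
longer of the two inter-repeat segments is labelled LSC and coordinates are
rotated so it starts at 0 (ties between equal-length maximal pairs are
broken toward the smallest start after rotation, with a warning).

Choices worth recording:

* **Exact repeats, 1 kb minimum.** Modern plastome assemblies emit the two
  IR copies as literal reverse complements, so allowing mismatches buys
  nothing and costs specificity; the 1 kb floor rejects tRNA-scale
  hairpins. `min_ir_len` is exposed for unusual genomes.
* **Rotation only, no strand flip.** On a circle the order
  LSC → IR → SSC → IR can always be reached by rotation alone; which IR copy
  is called "IRb" is a labelling convention.
* Detection is rotation-invariant by construction; the test suite asserts
  the region-length invariance under random rotations, and the mirror
  identity `revcomp(IRb) == IRa` is asserted byte-wise on every output.

GC content is `100 (G + C) / (A + C + G + T)` per region with the two IR
copies pooled; a region with no valid base reports `NA`. The
length-weighted mean of the region values equals the whole-genome value to
numerical precision (tested).

Junction offsets follow the IRscope convention: for each junction the
nearest tracked gene is reported with a positive offset equal to the
circular gap between the gene edge and the junction, or a negative offset
equal to the number of gene bases inside the IR when the gene straddles the
junction.

## Repeat scanning

`find_ssrs()` reports maximal perfect tandem repeats of 1–6 bp units with
per-unit minimum copy counts of 11, 6, 5, 4, 3, 3 — the conventional MISA
thresholds for plastomes. Only whole units count (`end − start =
unit × copies`); `N` breaks runs; a run is assigned to the smallest unit
that generates it (a poly-A run is a mononucleotide SSR, never `(AA)n`),
implemented by rejecting motifs that are themselves periodic. SSRs
separated by at most `compound_max_gap` (default 100 bp, the MISA default
— the source methodology does not state the value) merge into one
`compound` record; the `compound` flag can be turned off, because published
per-species totals are ambiguous about whether compound SSRs count as one
record or as their components, and the toggle lets either convention be
reproduced.

`find_long_repeats()` reports maximal exact repeat pairs ≥ `min_len`
(default 30 bp, with "longer than 30 bp" read as ≥ 30, the minimal-length
semantics of REPuter-style scanners) in four orientation classes: the
second copy equals the first (forward), its reversal (reverse), its
complement (complement) or its reverse complement (palindromic). Matching
is mismatch-free by default; repeats are found by the same seed-and-extend
engine as IR detection and de-duplicated so a pair contained in a longer
pair of the same class is suppressed. When a partition is available the
scan runs on LSC+IRb+SSC only — the convention of published plastome repeat
tables — which also removes the genome-scale IRa/IRb pair from the output.
Correctness is checked against a quadratic dynamic-programming oracle on
kilobase-scale sequences and against planted repeats with sanitised flanks.

## Nucleotide diversity and marker discovery

Per column, with `n_valid` characters in `{A,C,G,T}`, the comparable pairs
are `n_valid (n_valid − 1) / 2` and the differing pairs are counted from
the base tallies. Diversity over any column interval is the **ratio of
sums**: total differing pairs over total comparable pairs, columns with
fewer than two valid characters contributing zero to both sums, `NA` when
no comparable pair exists. This is the construction that stays unbiased
under alignment gaps; it is deliberately *not* the mean of per-column or
per-window values, and the test suite asserts the concatenation identity
`pi[a,c) = (D[a,b) + D[b,c)) / (C[a,b) + C[b,c))`.

Sites are classified as invariant, singleton, or parsimony-informative
(≥ 2 distinct valid bases each seen ≥ 2 times); gaps are never a fifth
state. Windows of 600 columns advance by 200 (both tunable); a window
qualifies as hypervariable when `pi > 0.01` **and** it has more than 25
parsimony-informative sites — strict inequalities, so boundary-equal
windows do not qualify. Maximal runs of consecutive qualifying windows
(consecutive in the step series; overlapping windows are inherently
adjacent) merge into one region spanning from the first window's start to
the last window's end, and the region's statistics are recomputed on the
merged span. Recomputation, rather than averaging window values, is the
choice consistent with published marker tables in which a merged region's
pi can fall below the window threshold.

Regions are reported in alignment columns; `name_region()` projects a
region onto a chosen annotated reference row by skipping the reference's
gap columns and labels it by the flanking (or containing) genes, the
`geneL-geneR` intergenic-spacer convention.

## Codon branch models

Codon alignments come from `back_translate()` (each aligned amino acid
replaced by its source codon, protein gaps becoming `---`, terminal stops
stripped, with a hard error on any translation mismatch) or from in-frame
nucleotide alignments. The genetic code is the bacterial/plastid table,
whose codon → amino-acid map coincides with the standard code.

The GY94 rate matrix over the 61 sense codons has
`q_ij = pi_j kappa^[ts] omega^[ns]` for single-nucleotide changes and 0
otherwise, scaled so branch lengths are expected substitutions per codon.
Equilibrium frequencies use the F3x4 scheme (positional nucleotide
frequencies multiplied, stops removed, renormalised) — the default of the
reference ML implementation in this field. The model is time-reversible;
likelihoods are computed by Felsenstein pruning in compiled code, with
per-node rescaling against underflow, transition matrices obtained from a
symmetrised eigendecomposition, and gap/ambiguous codons treated as fully
missing data (partial likelihood one over all states) rather than deleted
columns.

`fit_branch_model()` maximises the likelihood over log-transformed kappa,
omega(s) and all branch lengths with bounded quasi-Newton iterations
(`nlminb`), bounds `kappa ∈ [0.05, 500]`, `omega ∈ [1e-4, 99]`,
branch length `∈ [1e-7, 10]`. Input-tree branch lengths seed the optimiser
and are re-optimised per gene in both models (the reference
implementation's default behaviour). Three omega starting values
(0.1, 0.5, 1.5) guard against local optima, with deterministic seed-driven
jitter; `branch_model_lrt()` additionally warm-starts the two-ratio fit
from the one-ratio solution, which makes the nesting inequality
`lnL_alt ≥ lnL_null` hold in practice and cuts the cost of the second fit.
Eigendecompositions are cached within a fit because branch-length gradient
steps leave kappa and omega untouched.

The one-ratio (single ω) and two-ratio (foreground clade ωf, background ωb)
models differ by one parameter; `lrt()` refers `2ΔlnL` (clipped at zero) to
χ²(1). A significant test with ωf > 1 is classified as positive selection;
significant with ωb < ωf ≤ 1 as fast-evolving. The paper-style analysis
calls the comparison through `run_comparison()` with one codon alignment
per gene and the species tree.

## Synthetic data: what it emulates and what it does not

`simulate_plastome()` draws region sequences at a target GC (default 0.36,
a typical plastome value), plants SSRs, dispersed repeats and gene features
at recorded coordinates, writes IRa as the exact reverse complement of IRb,
and then *pins* every planted element: the bases flanking a planted repeat
are chosen so the repeat cannot extend by chance, and the bases flanking
the IR are chosen so the maximal inverted repeat is exactly the planted
one. This keeps the generator's truth table exact, which is what makes it
usable as an oracle.

`simulate_alignment()` mutates an ancestral row independently per sample
(star-tree-like) with a background substitution probability, an elevated
probability inside hotspot intervals, and i.i.d. gaps. Random draws are
made in fixed-size blocks per sample so that runs with the same seed but
different rates are monotonically coupled — raising the hotspot rate can
only add mutations, a property the test suite exploits. Because the
diversity estimator is tree-free, star-like simulation exercises it fully;
what this generator does *not* emulate is phylogenetic correlation,
indel blocks, or alignment error, so passing tests demonstrate estimator
correctness, not robustness to misalignment.

`simulate_codon_alignment()` evolves root codons drawn from the
equilibrium frequencies along the tree with per-branch transition matrices
from the same generator used for inference. Simulation and inference share
the rate-matrix code but not the likelihood path, and the pruning
likelihood is independently checked against exhaustive ancestral-state
summation on small trees.

## Problem sizes and runtime choices

The self-contained acceptance analyses use sizes chosen to make sampling
noise small relative to the tested tolerances while keeping a full run in
the minutes range on one core: 50 simulated plastomes (LSC 3–6 kb) for
architecture recovery; 100 random gapped alignments (≤ 10 × 200) against
the quadratic diversity oracle; kilobase sequences for the quadratic
repeat oracles; an 8-taxon tree with 500-codon genes and 20 replicates for
two-ratio power at (ωb = 0.2, ωf = 1.8); 2000 codons for one-ratio ω
recovery (±0.05); and 400 replicates of 200-codon 4-taxon null data for
LRT calibration, where the binomial standard error at a true 5% rate is
about 1.1%. Null-calibration and power replicates use a single omega start
(warm-started alternative fits): restart count is a robustness knob, not a
study condition, and one start converges to the same optimum on these
simulated likelihood surfaces.

## Known limitations

* IR detection assumes the two IR copies are exact mirror images; genomes
  with diverged IRs (or IR loss) are reported as "no quadripartite
  structure" rather than approximated.
* SSR scanning is strictly perfect-repeat (no TRF-style imperfect
  tandems); long-repeat scanning is exact-match by default.
* Site models and true branch-site models of selection are out of scope;
  only branch (one-ratio vs two-ratio) models are fitted, which is the
  df = 1 comparison the LRT here is built for.
* The diversity pipeline consumes an alignment as given; it does not
  realign, and between-population statistics (dxy, Fst) are not computed.
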