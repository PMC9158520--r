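# plastome

Comparative analysis of plastid (chloroplast) genomes in R, aimed at the
standard workflow used in plant comparative genomics papers: given a set of
complete plastomes (and optionally a whole-genome alignment and per-gene
codon alignments), characterise genome architecture, repeat content,
sequence divergence hotspots, and selective pressure on protein-coding
genes.

## What it computes

**Quadripartite structure.** A typical angiosperm plastome is a circular
molecule organised as LSC → IRb → SSC → IRa, where the two inverted repeats
(IRs) are exact reverse complements. `detect_inverted_repeats()` finds the
maximal pair of exact inverted repeats by seeded k-mer matching with
mismatch-free extension over the doubled circular sequence, labels the
longer inter-repeat segment LSC, and reports all four regions on the
canonical rotation (LSC starting at 0). `region_gc()` reports GC% per region
(N excluded from denominators) and `junction_report()` gives IRscope-style
signed offsets between the four junctions (JLB, JSB, JSA, JLA) and tracked
genes (`rps19`, `rpl2`, `trnH`, `ycf1`, `trnN`, `ndhF` by default): a gene
overlapping a junction gets a negative offset equal to the bases lying
inside the IR.

**Repeats.** `find_ssrs()` scans perfect microsatellites with MISA-style
per-unit thresholds (11, 6, 5, 4, 3, 3 copies for mono- through
hexanucleotide motifs), assigns each run to its smallest generating unit,
and merges SSRs separated by ≤ 100 bp into compound records.
`find_long_repeats()` reports maximal exact dispersed repeats ≥ 30 bp in
four orientation classes — forward, reverse, complement and palindromic
(reverse complement) — over the LSC+IRb+SSC portion, so the genome-scale
IR pair itself is never listed.

**Diversity hotspots.** For a multiple alignment, nucleotide diversity is
the gap-aware ratio-of-sums estimator

    pi = sum_sites(# differing pairs) / sum_sites(# comparable pairs)

where only `{A,C,G,T}` characters are comparable (gaps and N contribute
nothing — the "pixy-style" construction that stays unbiased under missing
data). `sliding_windows()` (600 bp windows, 200 bp step) and
`merge_hotspots()` join consecutive windows with `pi > 0.01` and more than
25 parsimony-informative sites into hypervariable regions, whose statistics
(length, singleton sites, parsimony-informative sites, pi) are recomputed on
the merged span. `name_region()` labels a region by its flanking genes on an
annotated reference (e.g. `trnH-psbA`).

**Selection.** `back_translate()` builds PAL2NAL-style codon alignments from
protein alignments plus unaligned CDS. The Goldman–Yang (GY94) codon model
with F3x4 equilibrium frequencies gives rates
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for
single-nucleotide codon changes; `fit_branch_model()` maximises the
Felsenstein-pruning likelihood over kappa, omega and all branch lengths, for
a one-ratio model (single ω) or a two-ratio branch model (foreground clade
ωf vs background ωb). `lrt()` compares them by `2ΔlnL ~ χ²(1)`; a
significant test with ωf > 1 flags positive selection, with ωb < ωf ≤ 1 a
fast-evolving gene.

**Simulators.** `simulate_plastome()`, `simulate_alignment()` and
`simulate_codon_alignment()` generate quadripartite genomes with planted
SSRs/repeats/genes, alignments with planted diversity hotspots, and codon
alignments evolved under branch-specific ω — all seed-deterministic and
returning ground truth, so every stage of the pipeline is testable offline.

`run_comparison()` orchestrates all stages over a directory of genomes from
a YAML or list configuration and writes TSV report tables plus a manifest.

## Worked example

```r
library(plastome)

sim <- simulate_plastome(list(
  lsc_len = 4000, ssc_len = 1000, ir_len = 1500, seed = 11,
  planted_ssrs = list(list(motif = "AT", copies = 6, region = "LSC")),
  planted_repeats = list(list(class = "forward", length = 40,
                              regions = c("LSC", "SSC")))))
part <- detect_inverted_repeats(sim$genome)
part
#> <quadripartite_partition> 8,000 bp: LSC 4,000 | IRb 1,500 | SSC 1,000 | IRa 1,500 (offset 0)
region_gc(sim$genome, part)
#> GC% total 36.59 (LSC 35.85 / SSC 38.10 / IR 37.07)
find_ssrs(sim$genome, part = part)
#>   motif unit_len copies start  end ssr_type region
#> 1    AT        2      6   400  412       p2    LSC
#> 2     A        1     11  5600 5611       p1    SSC
#> 3     T        1     13  6466 6479       p1    SSC
find_long_repeats(sim$genome, part = part)
#>         class length pos1 pos2 region1 region2
#> 1     forward     40  562 5761     LSC     SSC
#> 2 palindromic     35  752  937     LSC     LSC
```

The partition recovers the planted architecture exactly; the SSR table
contains the planted `(AT)6` at its truth coordinate 400 (plus a background
poly-T run the generator happened to draw), and the repeat table the planted
40 bp forward pair — the palindromic 35-mer is this seed's second planted
record. On a real accession the same calls take a `read_genbank()` /
`read_fasta()` genome and produce Table-style rows
(`structure_report(genome)`) and the junction, SSR and repeat tables.

For diversity, `sliding_windows()` + `merge_hotspots()` on a whole-genome
alignment produce the marker table written by
`write_regions(regions, "hotspots.tsv", "tsv")` with columns
`Start End Length #SVS #PIP Pi Gene name`.

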