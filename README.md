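# barcodive

Evaluation toolkit for DNA barcoding in recently diversified clades —
the hard case for barcodes, where shallow divergence, incomplete
lineage sorting (ILS) and introgression erode the "barcoding gap"
between intra- and inter-specific distances. It is written for people
who assess candidate barcode loci (single markers and combinations)
over a sampled genus: which marker, or panel of markers, recovers the
most species as monophyletic, and how often does nearest-neighbour
identification place a specimen in the right species?

## What it computes

* **K2P distances** with pairwise deletion and explicit masking of
  undefined (saturated / zero-overlap) pairs:
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`, with `P` the transition
  and `Q` the transversion proportion.
* **Barcoding-gap statistics**: intra- vs inter-specific distance
  pools, means and ranges, Mood's median test and the Wilcoxon rank-sum
  test (exact by enumeration for small samples), and histogram tables
  for plotting the two distributions.
* **Trees and resolution rates**: neighbor-joining and UPGMA with
  column-resampling bootstrap; per-species monophyly on rooted trees
  (clades) or unrooted trees (bipartitions); the percentage of species
  recovered as monophyletic, with a stricter rate requiring bootstrap
  support ≥ 70.
* **Leave-one-out identification** under three criteria: best match,
  best close match (95th-percentile intraspecific threshold), and all
  species barcodes.
* **Marker combinations**: gap-filled concatenation (or strict
  intersection), with a standard 22-combination design for five-marker
  panels, all orchestrated by `evaluate_combinations()`.
* **A multispecies-coalescent simulator** (`simulate_dataset()`):
  Yule species tree with compressible internal branches, per-marker
  coalescent gene trees (θ controls ILS), optional organelle-capture
  style introgression, K80 sequences at marker-specific rates, and
  per-marker dropout — producing truth-labeled datasets for validating
  the whole pipeline.

## Worked example

Simulate a 12-species, five-marker panel under radiation/ILS
conditions with occasional introgression, then evaluate two single
markers and the full supermatrix:

```r
library(barcodive)

cfg <- simulation_config(n_species = 12, seed = 2025, introgression_prob = 0.3)
sim <- simulate_dataset(cfg)
sim
#> synthetic_dataset: 12 species, 52 accessions, 5 markers, 3 introgression events
sim$event_log
#>      marker recipient    donor
#> 1      matK  Sim_sp12 Sim_sp11
#> 2 trnH-psbA  Sim_sp03 Sim_sp01
#> 3       ITS  Sim_sp02 Sim_sp10

report <- evaluate_combinations(
  sim$dataset,
  combos = list("rbcL", "ITS", names(sim$dataset$alignments)),
  methods = c("upgma", "nj"), n_boot = 100, seed = 99)

report$resolution
#>                           combo method n_species n_monophyletic n_supported rate rate_supported
#>                            rbcL  upgma        12              1           0  8.3            0.0
#>                            rbcL     nj        12              2           1 16.7            8.3
#>                             ITS  upgma        12              8           8 66.7           66.7
#>                             ITS     nj        12              8           8 66.7           66.7
#>  rbcL+matK+trnH-psbA+trnL-F+ITS  upgma        12              9           7 75.0           58.3
#>  rbcL+matK+trnH-psbA+trnL-F+ITS     nj        12              8           8 66.7           66.7
```

Reading the table: on this dataset the slow coding marker (rbcL-like)
recovers 1–2 of 12 species as monophyletic (8–17%), the fast nuclear
spacer (ITS-like) 8 of 12 (66.7%), and the five-marker supermatrix the
most (75% under UPGMA); `rate_supported` repeats the count restricted
to clades with bootstrap ≥ 70. Identification success follows the same
ordering:

```r
idt <- report$identification
idt[idt$criterion == "best_match", c("combo", "n_queries", "n_correct", "pct_correct")]
#>                           combo n_queries n_correct pct_correct
#>                            rbcL        51        39       76.47
#>                             ITS        52        42       80.77
#>  rbcL+matK+trnH-psbA+trnL-F+ITS        52        50       96.15

report$gap[["ITS"]]
#> gap_summary: #A (inter) = 1234, #B (intra) = 92
#>   mean intra 0.0169 (0.0000-0.0739), mean inter 0.0531 (0.0000-0.0808)
#>   median test p < 2.2e-16; Wilcoxon W = 14738.5, p < 2.2e-16
```

The gap summary shows the overlap typical of a recent radiation: the
intraspecific range (up to 0.074) reaches into the interspecific
distribution, which is why single-marker resolution stays far below
100% even though the two distributions differ significantly.

`write_evaluation_report(report, "out/")` writes the four TSV tables
(profile, gap, resolution, identification), per-distribution histogram
tables and the Newick trees. A thin command-line wrapper with
`evaluate` and `simulate` subcommands is installed under
`inst/scripts/barcodive-eval.R`. See the vignette
(`vignettes/barcode-evaluation-methods.Rmd`) for the models,
parameter meanings and design decisions.

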