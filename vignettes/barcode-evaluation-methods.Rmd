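---
title: "Evaluating DNA barcodes in recently diversified clades: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes in recently diversified clades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA barcoding assigns specimens to species using short standardized
sequences. The approach works when intraspecific variation is clearly
smaller than interspecific divergence — the "barcoding gap". In plant
genera that radiated recently, three processes erode that gap:
interspecific divergence is shallow (few substitutions separate sister
species), incomplete lineage sorting (ILS) lets gene trees disagree
stochastically with species boundaries, and hybridization or organelle
capture produces systematic cross-species associations. `barcodive`
implements the full distance-based evaluation toolkit used in such
studies — per-marker and multi-marker — together with a
multispecies-coalescent simulator so that every stage can be validated
on data with known truth.

# Distances

Pairwise divergence uses the Kimura 2-parameter model. With transition
proportion $P$ and transversion proportion $Q$ over the compared sites,

$$ d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q). $$

Two conventions matter and are deliberate:

* **Pairwise deletion.** Only columns where *both* sequences carry an
  unambiguous base (A/C/G/T) are compared. Gaps and IUPAC ambiguity
  codes are excluded per pair, not per column. This is the default of
  the distance software classically used for these analyses; alignments
  with heavy missing data therefore use different site sets for
  different pairs.
* **Undefined distances are masked, never imputed.** When a pair shares
  no sites, or when $1-2P-Q \le 0$ or $1-2Q \le 0$ (saturation), the
  entry is flagged undefined. Downstream tree construction *refuses*
  matrices containing masked entries rather than guessing values,
  because a silently imputed distance corrupts monophyly scoring. The
  bootstrap instead skips affected replicates and counts them.

# Gap statistics

All intraspecific and all interspecific pairwise distances are pooled
(each unordered pair once) and compared with two two-sample tests:
Mood's median test (Fisher's exact $p$ when any expected cell is below
5, chi-square otherwise) and the Wilcoxon rank-sum test. The Wilcoxon
$p$ is computed by exhaustive enumeration of rank assignments when the
pooled sample size is at most 12 (configurable) and by the
tie-corrected normal approximation with continuity correction
otherwise; reported values follow the conventional `< 2.2e-16` floor.
A caveat is documented rather than "fixed": pairwise distances are not
independent observations, so these $p$-values replicate the published
analysis procedure; they should be read as descriptive, not as exact
error rates.

# Trees and species resolution

Neighbor-joining (Q-criterion agglomeration) and UPGMA (average
linkage, via `hclust`) are built from the K2P matrix. Numerical
choices:

* NJ ties in $Q$ are broken by the lexicographically smallest label
  pair, making results deterministic; negative branch-length estimates
  are clamped to zero and flagged.
* NJ output is unrooted (basal trifurcation); UPGMA output is rooted
  and ultrametric. Monophyly is judged accordingly: on rooted trees a
  species is monophyletic iff some node's descendant set equals its
  accessions; on unrooted trees iff some edge's bipartition has one
  side equal to them (no outgroup is assumed). Singleton species are
  trivially monophyletic; the whole-tip set and size $n-1$ sets on
  unrooted trees are trivial splits and count as monophyletic.
* Bootstrap resamples alignment columns of the (possibly concatenated)
  matrix with replacement; an internal edge's support is the percentage
  of successful replicates containing its bipartition (clades for
  UPGMA, unrooted splits for NJ), rounded to the nearest integer.

The resolution rate of a tree is the percentage of species recovered as
monophyletic, with a second, stricter rate counting only species whose
subtending edge has bootstrap support at or above a threshold
(default 70). Singleton species are included in the raw rate — keeping
the denominator at the full species count, as the classical tabulations
do — but never in the supported rate, since no internal edge subtends a
single leaf. Both policies are explicit arguments.

A practical observation encoded in the test suite: when several
accessions are byte-identical, UPGMA necessarily merges them first,
while NJ's Q-criterion can attach one of them elsewhere when noise in
*distant* rows tilts the net-divergence terms. On very shallow data
UPGMA is therefore the more stable monophyly detector, consistent with
it being the strongest method in the classical comparisons.

# Identification criteria

Leave-one-out identification on the distance matrix, with three
criteria. Let the query's references be all other accessions, $B$ the
set of references at the minimum defined distance, and $S$ the
references within a distance threshold.

* **Best match** — correct if $B$ is entirely conspecific, incorrect if
  entirely heterospecific, ambiguous otherwise.
* **Best close match** — as best match, but `no_match` if the nearest
  reference lies beyond the threshold.
* **All species barcodes** — `no_conspecific` if the query has fewer
  than two conspecific references; otherwise correct only when $S$
  equals the query's full conspecific reference set; heterospecifics in
  $S$ give ambiguous/incorrect; a strict conspecific subset is
  incorrect.

The threshold is the nearest-rank 95th percentile (configurable) of all
intraspecific distances of the marker combination under evaluation,
computed per combination. Threshold comparisons are inclusive
(`<=`). Undefined distances are treated as farther than any defined
distance: a query can never match through a masked entry. By
construction best-close-match correct counts never exceed best-match
counts; no such ordering holds for all-species-barcodes, which is
strictly harder when intraspecific tails cross the threshold.

# Marker combinations

Combinations are evaluated by concatenating the selected markers
end-to-end. The default accession handling is the union with gap fill:
an accession missing a marker receives a full `-` block, which pairwise
deletion then ignores. This mirrors how multi-marker supermatrices are
assembled from unequal per-marker sampling. Its known failure mode is a
pair of accessions with *complementary* missing markers (no shared
sites): the pair is masked and the tree stage refuses the matrix. A
strict-intersection mode (`accessions = "intersection"`) is provided
for exactly that situation and for sensitivity analysis. The default
combination set for a five-marker panel is the classical 22-row design:
all singles, all pairs, the core pair plus each remaining single, the
core pair plus each remaining pair, and the full panel.

# The synthetic-data generator

The generator emulates a recently radiated, ILS-prone clade:

* **Species tree** — a Yule topology rescaled to root-to-tip depth
  `tree_depth`, expressed directly in expected substitutions/site at
  the slowest marker (no separate mutation-rate or generation-time
  layer; only relative rates matter to the evaluation). Internal node
  heights are then compressed toward the root so that every internal
  branch is multiplied by `radiation_scale` while the tree remains
  ultrametric — the coalescent needs contemporaneous tips, which a
  literal rescaling of internal branches alone would violate. At
  `radiation_scale = 0` the tree is a star phylogeny.
* **Gene trees** — one per marker under the multispecies coalescent:
  within each species-tree branch, $k$ lineages coalesce at rate
  $\binom{k}{2}/\theta$; survivors propagate rootward. $\theta = 0$
  forces concordance. ILS appears when $\theta$ is comparable to branch
  lengths.
* **Introgression** — with a per-marker probability, one event moves a
  recipient species' lineages onto the pendant edges of a donor
  species' samples (distinct donor tips while available). This is the
  organelle-capture-like pattern: whole-marker replacement producing a
  systematic association, and it guarantees the recipient is
  non-monophyletic in that gene tree. Recipient and donor are drawn
  among species with at least two samples.
* **Sequences** — K80 evolution (transition/transversion ratio
  `kappa`, default 2) with uniform root composition, consistent with
  the K2P distance used for analysis; sites are independent, no rate
  heterogeneity across sites, no indels. Missing data is modeled only
  as whole-marker dropout per accession (`missing_prob`).

## Default study conditions

The defaults describe a 47-species panel with 3–6 accessions per
species and five markers of lengths 1415, 847, 423, 927 and 668 bp with
relative rates 1, 2.25, 6.5, 1.9 and 9 (a slow coding plastid locus up
to a fast nuclear spacer). `tree_depth = 0.0015` and
`coalescent_theta = 0.001` were calibrated once so that simulated mean
intra-/inter-specific K2P distances land on the scale reported for real
radiated plant genera (about 0.002/0.004 at the slowest marker and
0.017/0.04 at the fastest); `radiation_scale = 0.3` keeps internal
branches short relative to $\theta$, which is what makes the regime
hard. Under these conditions the fast spacer-like marker resolves the
largest share of species among single markers, the slow coding marker
the least, and the five-marker supermatrix the most — the qualitative
pattern the pipeline is designed to quantify. One consequence worth
knowing: the coalescent gives intraspecific distances a heavy
exponential tail, so the 95th-percentile threshold can exceed much of
the interspecific distribution, and the all-species-barcodes criterion
then scores near zero. That is a statement about a vanished barcoding
gap, not a defect of the criterion.

What the generator does **not** emulate: indel variation (real
non-coding spacers gain length polymorphism that practitioners often
distrust for diagnosis anyway), among-site rate variation, linkage
between plastid markers (each marker draws an independent gene tree,
while real plastid loci share one history), polyploidy, and
base-composition bias. Passing tests on simulated data therefore
demonstrate correctness of the machinery and qualitative realism of the
regime, not quantitative prediction for any real genus.

## Problem sizes used in validation

The shipped validation suite runs, among others: exact-recovery checks
on 100 random additive and 100 random ultrametric matrices (6–12
taxa); oracle comparisons on 500 random trees (≤ 10 leaves) and 500
random toy datasets (≤ 8 sequences); a θ-sweep (20 seeds per value,
100 bootstrap replicates) on a 12-species single-marker design; and 25
seeded replicates of the full 47-species five-marker panel. These sizes
were chosen to exercise every code path at desk scale while keeping the
whole suite in the minutes range.

# Determinism

Every stochastic component takes an explicit integer seed, and
identical configurations produce byte-identical FASTA, Newick and TSV
outputs. Derived seeds for per-marker and per-combination work are
drawn from a seeded integer stream, so adding a marker does not
reshuffle another marker's draws.

# Known limitations

* The two-sample tests inherit the non-independence caveat above.
* NJ on matrices with many exactly tied, near-zero distances depends on
  the documented tie-break; other implementations may return different
  but equally valid resolutions of the ties.
* Maximum parsimony and maximum likelihood tree methods are out of
  scope; the toolkit covers the distance-based half of the classical
  comparisons.
* BLAST-style genus-level checks against external databases are out of
  scope.
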