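---
title: "Methods behind endomix: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind endomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`endomix` links airway microbiome community structure to sputum
inflammatory endotypes in longitudinal COPD cohorts. This vignette
documents the statistical machinery, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## Endotyping

Samples are classified from sputum differential cell counts by the
two-threshold rule: eosinophil-high at ≥ 3 % and neutrophil-high at
≥ 61 %, giving neutrophilic, eosinophilic, mixed-granulocytic and
paucigranulocytic subgroups. Both cutoffs are inclusive (`>=`), are
compared on unrounded percentages (whether source cohorts rounded before
thresholding is generally unreported, so no rounding is imposed), and are
configurable via `endotype_thresholds()`. A missing percentage yields
`"unassigned"` rather than an imputation: unassigned samples simply drop
out of endotype-conditional analyses, which conserves sample counts and
mirrors how incomplete cytology is handled in practice.

## Community typing

Community discovery works on the square root of the Jensen–Shannon
divergence between per-sample genus compositions, computed with base-2
logarithms (so the distance lies in [0, 1]) and the `0·log 0 = 0`
convention. The square root, not the raw divergence, is used because it
is a true metric, which hierarchical clustering semantics need.

"Ward" clustering on a non-Euclidean distance is ambiguous; we use
`hclust(method = "ward.D2")`, i.e. the Lance–Williams recursion on
squared dissimilarities, which is the standard Ward objective applied to
a metric. The caveat that √JSD is not Euclidean (so Ward's
variance-decomposition interpretation is approximate) is accepted, as is
conventional in enterotype-style analyses. The number of clusters is
chosen by the mean silhouette width of dendrogram cuts over k = 2..10,
ties resolved toward the smaller k. The k-medoids validation
(`validate_with_pam()`) is deliberately separate: PAM (build + swap, run
with 5 seeded random restarts because a single swap descent can stall in
a local optimum) is scored by a distance-based Calinski–Harabasz index,
and agreement with the Ward solution is reported as an adjusted Rand
index. Silhouette is attached to the hierarchical step and CH to PAM —
the two criteria are not mixed.

Clusters are named by dominance: a cluster whose top mean-abundance genus
exceeds 0.3 is `<Genus>-predominant`, otherwise `balanced`. The 0.3
default sits between typical dominated means (≈ 0.4–0.6) and balanced
top-genus means (≈ 0.15) and is exposed as an argument. Clustering is run
jointly on all samples by default; nothing prevents calling the pipeline
per cohort and comparing assignments.

`biomarker_threshold()` computes the AUC by the midrank Mann–Whitney
statistic (ties count one half) and picks the cutoff maximizing Youden's
J under the rule "positive when value ≥ cutoff", resolving ties toward
the lower cutoff so the reported threshold is the most sensitive of the
equally good ones.

## Ecology

Shannon diversity is reported in nats. Bray–Curtis, PCoA and PERMANOVA
follow their standard definitions; PERMANOVA uses the one-way pseudo-F on
squared distances with `p = (1 + #{F_perm ≥ F_obs}) / (n_perm + 1)` and a
seeded permutation stream. PCoA reports all eigenvalues, flags negative
ones, and leaves coordinates uncorrected; group dispersion instead uses
Anderson's imaginary-axis correction (via `vegan::betadisper`) because
distances to centroids are exactly where non-Euclidean distortion bites.
The dispersion group comparison uses rank-sum tests with BH adjustment —
the comparison statistic is not pinned down by convention, and rank-sum
on the per-sample distances is the least parametric choice.

Paired stability–exacerbation shifts pair each exacerbation with the
patient's **most recent preceding stable** sample. "Paired" alone does
not fix an ordering; preceding-stable matches a prospective design in
which the stable visit characterizes the patient's baseline state before
the event. Exacerbations with no prior stable visit are excluded, and
pairs are grouped by the stable sample's NH/NB/E state.

## Transitions

Transition tables count **consecutive** same-patient visit pairs in two
contexts (stable→stable, stable→exacerbation; pairs beginning at an
exacerbation are not analyzed). A pair is dropped when either member is
mixed, paucigranulocytic, unassigned, or neutrophilic with a
non-Haemophilus, non-balanced community. Pairs are never re-formed by
bridging across an excluded visit: bridging mixes one-step and multi-step
transitions and biases persistence estimates (for the default generator
the NB persistence would be inflated by roughly 0.09), whereas dropping
keeps the estimator consistent for the one-step transition probabilities.
The `adjacency = "consecutive"` field records this.

Covariate–switch odds ratios use `ad/bc` with the Haldane–Anscombe +0.5
correction on any zero cell (flagged), Woolf log-normal 95 % intervals,
and a z-test p-value. "Seasonal change" is defined as the two visits of a
pair falling in different meteorological quarters, computed from visit
dates — no standard definition exists, so the simplest calendar-based one
is used and the season is carried in the metadata.

## Changepoints and cross-covariance

`pelt_changepoints()` implements the PELT recursion for the normal
mean-change cost (within-segment sum of squared deviations) with a
minimum segment length of 2. The default penalty is BIC-style,
`2·σ̂²·log n`, with σ̂² estimated from first differences
(`var(diff(x))/2`), which stays robust when the series contains genuine
level shifts. One numerical subtlety matters: under a minimum segment
length, a candidate pruned at time *t* is dominated by *t* itself only
from `t + min_seg` onward, so pruning removals are applied with that
delay; this preserves PELT's exactness, which the test suite verifies
against exhaustive enumeration for hundreds of short series (length ≤
12, the realistic visit-count regime). A constant series yields an empty
changepoint set.

For changepoint–event association, an inter-visit transition "contains" a
changepoint when a new segment starts exactly at the destination visit —
the tightest reading of a break coinciding with a clinical event. Events
are either exacerbation occurrence at the destination visit, or an
endotype switch between two consecutive stable visits (each direction
separately); patients need ≥ 5 visits. The pooled 2×2 table across all
eligible transitions gives one odds ratio per genus, called significant
only when the lower 95 % limit exceeds 1.

The cross-covariance score z-scores both series by their full-series
standard deviations and takes the **signed maximum** of the normalized
cross-correlation over lags |ℓ| ≤ 1 (positive lag = abundance leads).
Sparse, irregular visit schedules make longer lags uninterpretable; the
signed maximum (rather than lag-0 or an absolute maximum) keeps
directionality while allowing a one-visit lead or lag, and the convention
is recorded here because the underlying choice is not standardized. The
permutation null permutes the abundance series order within patient,
preserving each patient's marginal distribution, and significance is a
one-sided rank-sum test of observed per-patient scores against the pooled
permuted scores (`paired = TRUE` switches to comparing each patient with
the mean of its own null). The pooled variant's type-I error is checked
by simulation (500 null cohorts) in the acceptance suite.

## Networks

`sparcc()` follows the reference algorithm: 20 estimation iterations,
each drawing fractions from the per-sample Dirichlet posterior
(pseudo-count 1), computing the variation matrix `t_ij = var(log x_i/x_j)`,
solving the sparse linear approximation for basis variances, and
iteratively excluding the most extreme pair with |r| > 0.1 (up to 10
rounds); the final correlation is the elementwise median across
iterations, clipped to [−1, 1]. Edge significance re-runs SparCC on
column-permuted tables; note that at very high sequencing depth this
permutation null becomes conservative (the permuted tables have slightly
wider log-ratio spread than the observed one), which preserves FDR
control but costs power — the calibration checks therefore run at a
realistic depth. Louvain module detection is order-dependent, so it is
run with 10 seeded restarts keeping the best modularity, at resolution
1.0. Genus–mediator association residualizes both sides with a linear
mixed model (demographic covariates as fixed effects, patient as a random
intercept; the covariate set is an argument because no canonical set
exists) and then tests all pairs flat with Spearman correlation and BH
adjustment — a deliberate simplification of hierarchical all-against-all
testing: the residualization is kept faithful, the hierarchical testing
layer is replaced by the flat screen.

## The synthetic-cohort generator

`generator_config()` defines the emulated study conditions. Patients get
1–13 visits (truncated geometric, mean ≈ 3.3), a stable baseline visit,
and exacerbation visits at rate 0.33. Inflammatory states follow a
five-state Markov chain (NH, NB, E, plus MIXED and PAUCI so that
downstream exclusion rules are exercisable); stable-visit persistences
default to 0.714 / 0.384 / 0.418 and exacerbation-visit persistences to
0.591 / 0.214 / 0.333 with a 0.476 NB→NH switch mass. The NH/NB/E rows
place no mass on MIXED/PAUCI: this makes the configured persistences
recoverable both as raw chain frequencies and after excluded-pair
dropping, while mixed/paucigranulocytic samples still arise from the
initial state distribution, the MIXED/PAUCI rows, and cell-count noise
pushing measured endotypes across the 3 %/61 % thresholds.

Compositions are Dirichlet draws: a balanced profile (top genus mean
0.14; *Veillonella* + *Prevotella* combined mean 0.26; total precision
180) and dominated profiles with dominant-genus mean 0.6 at precision
150. Precisions are **not** cohort-calibrated — the source material for
this kind of analysis reports no composition variance — and were fixed
once so that between-type separation exceeds within-type spread, which is
the regime the clustering-recovery checks assume. Two covariance
mechanisms create realistic network structure: a per-sample dominance
factor scales the dominant genus up and a weighted anaerobe subset down
(giving the dominant genus identifiable co-exclusion edges — a factor
loading uniformly on *all* other genera would be compositionally
unidentifiable and invisible to SparCC), and a shared latent factor
couples *Campylobacter*/*Granulicatella* (loading 0.8) and
*Capnocytophaga*/*Fusobacterium* (loading 0.5) to sputum eosinophilia,
powering the cross-covariance and eosinophilic-clique analyses.

Cell percentages are independent truncated normals per class with the
granulocyte pair (neutrophils + eosinophils) jointly renormalized to at
most 100. Truncation and renormalization pull realized means below their
targets (the neutrophilic-Haemophilus class means are large enough for
both to bite), so latent class means are calibrated at configuration time
by stochastic approximation against the actual sampling mechanism, under
a fixed internal seed: emitted means match the configured values; the
realized standard deviations shrink slightly under truncation and are
left uncalibrated. Mediators are drawn directly on the log scale from
per-state normal distributions; no back-transform is applied.

What the generator does **not** emulate: read-level sequencing error and
batch structure (inputs are post-taxonomy genus tables; the upstream
batch-correction step of real pipelines is documented but not modeled),
phylogenetic relatedness, infection status beyond the visit-type flag,
site effects on composition, and irregular within-patient correlation of
visit times. Passing tests therefore demonstrate correctness of the
statistical machinery under a known generative model, not robustness to
every artifact of real cohort data.

## Problem sizes and numerical conventions

The default test and acceptance runs use cohorts of 200 patients (≈ 650
samples), ~10,000 transition pairs for persistence recovery, 500-replicate
null simulations for calibration checks, and exhaustive-oracle suites at
n ≤ 12 (segmentations), n = 6 (medoids) and n ≤ 10 (silhouette/CH) —
sizes at which brute force is exact and fast. Relative-abundance rows
must sum to 1 within 1e-6 on input and are produced summing to 1 within
1e-9; distance matrices are validated symmetric within 1e-8; zero-sum
samples, all-zero genera, constant indicators, single-sample groups and
single-visit-only cohorts all produce errors or explicit degraded modes
(warnings) rather than silent results. All stochastic steps (rarefaction,
permutations, bootstraps, Louvain restarts, the generator itself) take
explicit seeds and restore the caller's RNG state.

## Known limitations

- Ward-on-√JSD and centroid dispersion inherit the usual caveats of
  non-Euclidean dissimilarities.
- The LEfSe-style effect size omits the subclass (within-class Wilcoxon)
  stage — the designs targeted here have no subclass structure — and
  gates on BH-adjusted p by default (`fdr = FALSE` restores the classic
  raw-alpha behavior).
- The SparCC permutation null is conservative at very high depth (see
  above).
- The cross-covariance score treats visits as equally spaced; strongly
  irregular sampling would call for continuous-time methods out of scope
  here.
- Mixed-model marginal R² uses the fixed-effect variance over total
  variance; with few patients the random-intercept variance is estimated
  noisily and the ratio inherits that noise.
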