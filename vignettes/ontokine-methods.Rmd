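---
title: "Methods: from multiplex plates to trajectory clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiplex plates to trajectory clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ontokine implements an analysis pipeline for longitudinal plasma
cytokine/chemokine panels measured on bead-based multiplex immunoassay
plates, aimed at the neonatal setting: each participant is sampled at birth
(day of life 0) and once more at DOL 1, 3 or 7, and the question is how the
circulating analyte milieu moves across the first week of life. The
pipeline runs from raw plate exports (median fluorescence intensity per
well and bead region) to a consensus clustering of analyte trajectories,
with every intermediate quantity exposed as a tibble.

This vignette records the statistical models, the defaults, and the design
decisions that were genuinely open, in that order of stage.

## Quantification from standard curves

Each plate carries a dilution ladder (8 standards, 4-fold steps by
default) and blank wells per analyte. Three response families are fitted
by least squares on log10(MFI):

* four-parameter logistic (4PL): `mfi(x) = d + (a - d) / (1 + (x/c)^-b)`
  with lower/upper asymptotes `d`, `a`, inflection concentration `c` and
  slope `b`;
* five-parameter logistic (5PL), which raises the denominator to an
  asymmetry power `g`;
* a power-law ("exponential") fallback, linear in log-log space.

The family is selected per (plate, analyte) by AIC on the log10(MFI)
residuals (`criterion = "sse"` is available). AIC rather than raw SSE is
the default because the 5PL nests the 4PL: on data a 4PL explains fully,
the extra parameter must pay for itself. Numerically, residual sums of
squares are floored at a machine-noise level before entering the AIC so
that two interpolating fits tie and the parameter penalty decides.

Fitting uses Levenberg–Marquardt on log-scale parameters
(`log a, log d, log c, b[, log g]`), which keeps the Jacobian
well-conditioned when asymptotes in the tens of thousands sit next to a
unit slope and makes positivity automatic. Two data-driven starts are
always tried — one with the floor just below the smallest observed MFI,
one with a near-zero floor, because a ladder that never reaches the lower
plateau badly misleads the first guess — followed by seeded jittered
restarts only if neither start explains more than 99.9% of the response
variance. A flat ladder (no MFI response) is a hard error; a series where
no family converges is flagged and excluded rather than silently dropped.

Detection and quantification limits follow the conventional immunoassay
definitions, since the workflow being reproduced delegates them to an
assay-processing package without stating formulas:

* lower limit of detection (LLD): concentration at mean(blank) + 3·SD(blank);
* upper limit of detection (ULD): concentration at 95% of the fitted
  asymptote span;
* LLOQ/ULOQ: the outermost standards whose back-calculated recovery first
  falls within 70–130% when sweeping inward from the ladder ends.

The ordering `lld <= lloq < uloq <= uld` is enforced by widening the
detection limits if necessary. Wells with fewer than 30 beads are
discarded outright. Remaining wells are inverted through the curve and
multiplied by the dilution factor (2, for plasma diluted 1:2); values
outside the quantification range are imputed at the corresponding limit of
quantification *before* the dilution factor is applied (the source
workflow does not state the order; imputing on the well scale keeps the
limits in the units they were estimated in). Samples whose every
informative analyte sits below the LLD are excluded with a log message.

Discarded low-bead wells propagate as missing cells. All downstream stages
are missing-tolerant (moments over observed cells, pairwise-complete
tests); the PCA summary, which needs complete rows, drops incomplete
samples and reports how many. No imputation beyond the censoring rules is
performed.

## Normalization

Concentrations are log10-transformed. Plate (batch) effects are removed by
a parametric empirical-Bayes location/scale adjustment — per-analyte
standardization, per-plate mean and variance estimates shrunk toward
pooled priors by the standard iterative EB update, then removal. The
algorithm is implemented in the package (it is part of the contract being
reproduced); `sva::ComBat` serves as an independent cross-check in the
test suite, where the two agree to ~1e-6 on complete data. No covariates
enter the batch model: the synthetic design keeps plates unconfounded with
visit and DOL, so protecting a covariate is unnecessary.

Two properties worth stating honestly:

* The EB estimator is *not* exactly idempotent. Shrinkage deliberately
  leaves a small residual batch effect (on the order of the batch-mean
  estimation noise), and a second pass removes part of that remainder.
  The tests assert the honest contraction property — a second pass
  perturbs cells an order of magnitude less than the first, and by a
  small absolute amount — rather than exact idempotence.
* Per-analyte per-plate *variance ratios* after correction retain the
  sampling noise of a variance estimate at the plate size; what the
  correction equalizes is the systematic scale component. Tests measure
  the systematic part (means over analytes) at cohort-like plate sizes
  (~170 samples per plate).

Bridge samples — aliquots of one reference pool run on every plate — are
used for QC only, not as anchors in the correction: the source workflow
describes a bridge set without an algorithm, and EB correction plus bridge
QC is the most conservative reading. The QC reports the across-plate SD of
plate-level bridge means before and after correction and flags analytes
that got worse.

Analytes with near-zero variance are excluded by the standard two-part
rule: frequency ratio of the two most common values above 95/5 *and*
percentage of unique values below 10 (the conventional defaults of the
filter the source workflow names without thresholds). This targets
floor-censored analytes whose cells sit almost entirely at the imputed
LLOQ. **Order matters**: the filter runs *before* batch correction by
default. The censoring signature is a massive tie at one value (the LLOQ
imputation lands on the same standards-ladder concentration on every
plate); EB correction maps those ties to plate-specific values and
destroys the frequency-ratio signal. Filtering first is therefore the only
order under which the filter can do the job it is named for;
`nzv_after_combat = TRUE` restores the other order for data where it is
appropriate. On the default synthetic cohort the filter removes exactly
the three planted floor-censored analytes (IL-2, IL-3, IL-17A), retaining
38 of 41.

## Ontogeny statistics

Fold changes index each participant's follow-up concentration to their own
DOL0 value on the untransformed scale, then take log10 (log2 carried
alongside for the volcano criterion). Per analyte and follow-up day, a
two-sided paired Wilcoxon signed-rank test compares the normalized log10
values; zero differences are dropped (Wilcoxon's rule), the exact null
distribution is used up to n = 25 untied pairs, and the normal
approximation with tie and continuity corrections beyond. Two-sided tests
throughout: both increases and decreases are of interest and no direction
is privileged.

Multiple testing uses Holm's step-down with the family size fixed at the
retained-analyte count (38 by default) for every follow-up day, mirroring
an analysis that adjusts per day over the full analyte roster. The
volcano criterion flags contrasts with raw p < 0.01 and |log2 fold change|
> 0.2; both thresholds are arguments (a looser p < 0.05 convention exists
for the univariate summaries, and both are exposed rather than reconciled).

PCA summarizes the normalized matrix with every analyte centered and
scaled to unit variance. Covariate association fits, per analyte, an OLS
model of the normalized value on the covariate, a visit term (birth vs
follow-up) and their interaction, with Holm adjustment per term across
analytes; rank-deficient designs are flagged and skipped. Cluster-level
paired t-tests compare, per trajectory cluster and follow-up day, the
per-participant mean standardized value at DOL0 versus follow-up, with a
95% confidence interval of the cluster mean per DOL; clusters with fewer
than 3 complete pairs get the interval only.

## Trajectory clustering

Standardization z-scores each analyte over all study samples pooled across
visits. Pooling (rather than within-visit standardization) is deliberate:
within-visit z-scoring would erase exactly the visit contrast the
trajectories are meant to display. Mean 4-point series over DOL {0, 1, 3,
7} are formed per analyte — the DOL0 mean over all participants, each
follow-up mean over its subgroup.

Distances between series use dynamic time warping: the dynamic-programming
global alignment cost with absolute-difference local cost, both endpoints
matched, full window. The default step pattern uses unit weights for the
three moves {(1,0), (0,1), (1,1)}; the classic `symmetric2` pattern
(diagonal weight 2) is available, and the planted-recovery tests pass
under both. Series are indexed by visit order; the calendar spacing
(0, 1, 3, 7) does not weight the alignment — the distance treats the
series as 4-vectors, matching a plain DTW call. DTW is not a metric (no
triangle inequality), which is fine for hierarchical clustering.

Complete-linkage agglomerative clustering is applied to the distance
matrix (rows kept in lexicographic analyte order, which pins merge order
under ties). The number of clusters is chosen by maximizing the average
silhouette width over k in 2..8, with ties to the smaller k and the
`s(i) = 0` convention for singleton clusters.

Robustness is assessed by bootstrap consensus: B resamples (default 1000)
of 90% of the participants drawn *without replacement* (the stated
protocol gives both "90%" and a count that is not 90% of the cohort; the
fraction is primary here and the count is `floor(frac * n)` — 547 of 608
at defaults). Each resample rebuilds standardization, trajectories,
distances and the complete-linkage cut; co-clustering indicators average
into the consensus matrix M; final labels cut the complete-linkage tree of
1 − M at k; cluster stability is the mean within-cluster off-diagonal
entry of M. k is selected once on the full data and held fixed across
resamples — re-selecting per resample is available, but a fixed k is what
makes "co-clustering frequency" a well-defined quantity across runs. Every
resample's RNG stream derives from the master seed plus the run index, so
runs are reproducible and order-independent. A resample that empties a DOL
subgroup is redrawn and logged (impossible at the default sizes, relevant
for toy configurations).

The validation methodology re-runs the consensus machinery without
averaging: each resample clusters analytes on the distance obtained by
averaging, over resampled participants, the DTW distance between the
two-point (DOL0, follow-up) standardized series of each analyte pair. For
aligned two-point series the DTW cost reduces exactly to the sum of the
per-visit absolute differences, which is what the vectorized
implementation computes. This construction is one faithful reading of an
under-specified validation protocol ("the two time points from each
individual, without averaging"); agreement with the primary clustering is
reported as the adjusted Rand index. Because per-participant series carry
the full biological noise — and because analytes whose classes differ only
at DOL1 are indistinguishable in the two-point series of DOL3/DOL7
participants — the individual-level consensus sits systematically below
the trajectory-averaged one, reproducing the qualitative ordering reported
for the motivating cohort (79.4% vs 53.9% there).

## The synthetic cohort generator

The generator is first-class, tested code; it exists so that every stage
has ground truth. The forward model per study sample is

```
log10 conc = baseline(analyte) + delta(archetype, DOL)
           + participant effect + residual
```

with plate batch effects (location + scale) applied on the
log10-concentration scale to sample and bridge wells, a per-analyte 4PL
curve mapping the diluted well concentration to MFI, plate-level assay
drift on log10(MFI) applied to *all* wells including standards (and hence
absorbed by the curves), and multiplicative log-normal MFI noise.

Defaults emulate the motivating study's conditions: 608 participants (202
/206/200 follow-ups at DOL 1/3/7, block-randomized), 41 analytes on 7
plates, three analytes (IL-2, IL-3, IL-17A) planted at a concentration
floor far below detection, and five kinetic archetypes:

| class | shape | deltas at DOL 0/1/3/7 (SD units) |
|---|---|---|
| 1 | flat, transient DOL1 trough | 0, −0.5, 0, 0 |
| 2 | flat, transient DOL1 peak | 0, +0.5, 0, 0 |
| 3 | slow rise | 0, +0.2, +0.5, +0.8 |
| 4 | steady decrease | 0, −0.4, −0.8, −1.1 |
| 5 | sharp DOL1 rise, reversal by DOL3 | 0, +1.2, +0.8, +0.5 |

The shapes are transcribed from the qualitative cluster descriptions of
the motivating study; the magnitudes are generator parameters, not
estimates. They were calibrated once, before the acceptance suite was
frozen, to the stated recoverability target — silhouette selection must
return k = 5 reliably with an average silhouette width in the
"recoverable but not trivial" band (0.3–0.7). Two geometric facts drove
the calibration: the per-DOL mean estimation noise is fixed at ~1/sqrt(202)
standardized units regardless of any noise knob (standardization makes
per-sample SD 1), so classes 1 and 2 need a ±0.5 excursion to stay
separable; and DTW's warping lets the original class-5 shape shadow
class 2, so class 5's peak was raised to +1.2. Per-analyte jitter
(SD 0.07 in delta units at each follow-up DOL) provides the within-class
heterogeneity visible in real cluster traces. With these defaults, 20/20
calibration seeds selected k = 5 with ASW 0.64–0.75 and ARI ≥ 0.95
against the planted partition.

Noise defaults: participant random effect SD 0.15 and residual SD 0.15 on
log10 pg/mL (their quadrature sum, ~0.21, is the "SD unit" of the delta
table — in line with the reproducibility of plasma cytokine panels); MFI
noise 5% (log-normal); standards/blank noise 2%; plate batch effects with
location SD 0.15 (plate-wide) plus 0.10 (analyte-specific — matrix effects
on real multiplex plates differ by analyte, and an analyte-specific
component is also what makes the per-analyte EB estimates well-determined
rather than pure shrinkage targets); log-scale SD 0.10; assay drift SD
0.05. Bead counts are negative-binomial around 75 with a 0.2% low-bead
probability. Curve inflections are drawn near each analyte's typical well
concentration (assays are designed so samples fall mid-curve); censored
analytes get an ordinary curve so their planted signal sits at its floor.
The bridge pool sits at the analyte baselines — a pooled reference plasma
naturally sits at cohort-average levels, which also keeps bridge wells in
the well-conditioned part of the curve.

Participants are assigned to plates round-robin by enrollment order with
*both* of a participant's samples on the same plate. Sample-level
round-robin looks natural but confounds visit with plate whenever the
plate count divides the samples-per-participant pattern (with 2 plates,
every birth sample lands on plate 1 — and the batch correction would then
remove the visit effect wholesale); participant-level assignment keeps
visit and DOL composition balanced across plates for any plate count.

Covariates (sex, gestational category, maternal age band, ethnicity,
breastfeeding) are generated with zero effect by default, matching the
null associations of the motivating cohort; a `sex_effect` knob plants a
log10 main effect for power tests.

What the generator does *not* emulate: real analytes' absolute pg/mL
ranges, between-analyte correlation beyond cluster membership, missing
visits/dropout, plate layout artifacts (edge effects, carryover), and
non-Gaussian heavy-tailed biology. Passing tests therefore demonstrate
that the pipeline recovers structure of the planted kind at realistic
noise — not that any particular real dataset has that structure.

## Numerical choices and degenerate inputs

* Curve fits floor RSS at machine-noise level inside the AIC; flat ladders
  error; non-convergent (plate, analyte) pairs are flagged `ok = FALSE`.
* Inverse curves map MFI at/beyond the asymptotes to 0/Inf so the
  censoring rules, not the inverter, decide the outcome.
* EB correction floors degenerate variance estimates at 1e-8 with a
  warning; a single batch is the identity; iteration converges at 1e-6
  relative change.
* Silhouette: singletons take s = 0; k ties resolve to the smaller k;
  distance-matrix validity (symmetry, zero diagonal, nonnegativity) is
  checked on entry.
* Identical partitions (including all-singletons, where the
  chance-corrected denominator vanishes) have adjusted Rand index 1 by
  convention.
* All bootstrap seeds derive from `master seed` and run index and stay
  below 2^31; seeded sections never disturb the caller's RNG stream.

## Problem sizes used by the test suite

Unit tests run a scaled-down cohort (120 participants, 3 plates, full
41-analyte panel) plus analytically tractable toys; enumeration oracles
(sign-flip Wilcoxon, step-down Holm, exhaustive DTW paths) run at full
stated sizes. The simulation-based checks of headline behavior run at the
full default conditions: 50 seeded cohorts for the k-selection and
planted-recovery rates, 20 for the consensus ordering (B = 50 per mode),
5 for the bridge-QC reduction, 100 replicates for curve recovery. The
acceptance script runs one full pipeline at B = 100 per consensus mode.

## Known limitations

* The EB batch model assumes Gaussian location/scale effects; wildly
  non-Gaussian batch artifacts would need the nonparametric variant,
  which is out of scope.
* LOD/LOQ definitions are the conventional ones; kits whose vendors
  define limits differently will disagree in the censoring band.
* The individual-level validation distance is one reading of an
  under-specified protocol; other constructions (e.g. Monti-style
  item-resampling consensus) are defensible and would change the absolute
  consensus values, though not the averaged-vs-individual ordering logic.
* With only four time points, DTW's advantage over Euclidean distance is
  modest; the step-pattern switch exists precisely so that sensitivity to
  this choice can be checked.
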