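---
title: "Measuring mRNA half-lives from 4TU pulse-chase labeling: models and methods"
author: "tuChase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mRNA half-lives from 4TU pulse-chase labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuChase)
```

## The measurement and its model

Metabolic labeling with 4-thiouracil (4TU) measures mRNA turnover without
shutting off transcription. At the chase start (t = 0) 4TU is added; RNA made
afterwards incorporates the thiolated base, is biotinylated, and is pulled
out on streptavidin beads. The unlabeled flowthrough is therefore the
pre-existing mRNA pool, which decays; the labeled eluate is newly made mRNA,
which accumulates. Each timepoint is anchored by exogenous spike-in RNAs
added in constant amount before extraction (one per channel), which absorb
differences in recovery and sequencing depth between libraries.

Labeling, biotin conjugation and bead separation are not perfect. If a
fraction `1 - eff` of newly made RNA escapes capture, it contaminates the
unlabeled channel, where at steady state it looks like a non-decaying
baseline. For a transcript at steady state with abundance `A`, half-life
`Th` and bulk capture efficiency `eff`, the noiseless unlabeled signal is

    U(t) = A * (eff * 2^(-t/Th) + (1 - eff))

and after spike and t = 0 normalization the fitted decay model is

    RNA(t) = eff * 2^(-t/Th) + (1 - eff).

Ignoring the efficiency term (fitting a plain exponential, `eff` fixed at 1)
mistakes the baseline for slow decay and overestimates `Th`; the bias grows
as `eff` falls. `inefficiencyBias()` reproduces this on noiseless data:

```{r bias}
inefficiencyBias(effs = c(1, 0.9, 0.8, 0.6), halfLife = 5)
```

The labeled channel accumulates as `L(t) = eff * A * (1 - 2^(-t/Th))`, which
over a short chase is close to linear; the synthesis model is an ordinary
least-squares line `RNA(t) = ks * t + offset` whose slope estimates the
(efficiency-scaled) synthesis rate `eff * A * ln(2) / Th`.

## Normalization

Decay-channel series are divided by the spike signal at each timepoint and
then by their own t = 0 value, so every fitted series starts at exactly 1.
Synthesis-channel series are spike-normalized only: their t = 0 signal is
essentially zero (no label exists before the pulse), so dividing by it would
be numerically meaningless; the linear fit absorbs the scale instead
(`t0Normalize(..., force = TRUE)` overrides this if both normalizations are
wanted). Replicates are always normalized and fitted independently;
agreement is assessed afterwards on the fitted half-lives.

A transcript whose t = 0 signal is zero cannot be anchored. At the
experiment level such rows are flagged (`rowData()$zero_anchor`) rather than
raising an error, and they surface as `unfit` in the fit table.

## Fitting

For fixed `Th` the decay model is linear in `eff`, so the conditionally
optimal efficiency has the closed form
`eff*(Th) = sum((y-1)(x-1)) / sum((x-1)^2)` with `x = 2^(-t/Th)`, clamped to
its bounds (the sum of squares is convex in `eff`, so clamping preserves
conditional optimality). The two-parameter fit therefore reduces to a
one-dimensional profile over `Th`, which `fitDecay()` minimizes with a
log-spaced grid scan (240 points over the `Th` bounds by default) followed
by Brent refinement inside the bracketing cells (tolerance 1e-10). This is
deterministic — no random restarts — and reaches the global bounded optimum
up to grid resolution; on noiseless model data it recovers `Th` and `eff` to
better than 1e-6, and its residual sum of squares never exceeds that of an
exhaustive two-dimensional grid search. `fitTranscriptome()` vectorizes the
grid stage across all transcripts (each grid half-life costs one matrix
product), which makes a 5000-transcript transcriptome fit in a few seconds.

Defaults, all configurable via `fitConfig()`:

* `Th` bounds 0.1–600 min. The lower bound is far below any measurable
  half-life on a minutes-scale grid; the upper bound exceeds a yeast cell
  cycle several-fold. Hitting a bound is recorded as a flag, not an error.
* `eff` bounds 0.01–1: an efficiency of zero would make the model
  unidentifiable (a flat line).
* R-squared is computed on the normalized values, including the t = 0
  anchor, about the series mean.
* Status thresholds: fits with R² < 0.8 are `poor_fit`; R² > 0.95 earns a
  `high_quality` flag; series the optimizer cannot use (constant, or
  zero-anchored) are `unfit`; transcripts whose mean spike-normalized signal
  is below 1e-3 of the spike are `low_expression` and are excluded before
  fit quality is judged. The R² cutoffs are the conventional reporting
  thresholds for this assay; the expression cutoff has no published value
  and 1e-3 was chosen as a level at which a minutes-scale time course is
  dominated by background.

## Transcriptome summaries

`summarizeHalfLives()` reports the mean and median half-life over `ok` fits,
the fractions of transcripts with `eff` above 0.9 and 0.8, and the fraction
of fits with R² above 0.95. `meanLifetime()` converts a half-life to a mean
lifetime (`Th / ln 2`). `bulkHalfLife()` sums spike-normalized signals over
transcripts before normalizing and fitting, so abundant transcripts carry
proportional weight: because many of the longest-lived transcripts are
highly abundant, the bulk half-life exceeds the unweighted mean.
`replicateAgreement()` computes Pearson correlation of half-lives between
replicates on log10 values by default — the distribution spans more than an
order of magnitude, and linear-space correlation is dominated by the
long-lived tail; a linear option is retained since either convention is
defensible. `longLivedSet()` takes the sample (n−1) standard deviation for
its mean + k·SD cutoff.

## Perturbation comparisons

Two mechanistic models make opposite predictions for how translation
inhibitors change mRNA stability. Stalled-ribosome-triggered decay predicts
destabilization when elongation is slowed; translation-factor protection
predicts stabilization when elongation is slowed and destabilization when
initiation is inhibited (the stalled-ribosome model makes no clear
prediction for initiation inhibition, so no p-value is produced for that
combination). `pairedModelTest()` evaluates one direction as a one-sided
paired t-test on half-life differences; the caller maps (perturbation,
model) to a direction. Tests are run on raw half-life differences by
default, matching how per-transcript half-life pairs are reported, with a
log option. The pairing axis is the caller's choice: replicate-level
estimates of one transcript, or per-transcript values across a
transcriptome — both are plain paired vectors.

`wilcoxonPaired()` is the transcriptome-wide two-sided paired signed-rank
test. Zero differences are dropped; ties take average ranks. With up to 25
informative pairs the p-value is exact: average ranks doubled are integers,
so the full sign-flip null distribution is built by convolution. Above 25
pairs a normal approximation with tie and continuity corrections is used.
The two-sided exact p is `2 * min(P(W <= w), P(W >= w))`, capped at 1.

`halfLifeEcdf()` produces the cumulative half-life distributions used to
display global stabilization or destabilization;
`crossConditionSpearman()` checks that a perturbation shifted the stability
profile rather than reordering it; `foldChangeByCount()` summarizes
half-life fold changes above and below a codon-count threshold (e.g.
histidine + glycine codons under histidine starvation, where a threshold
effect appears above 2).

## Feature correlations

`spearmanMatrix()` computes pairwise Spearman correlations among
per-transcript features (half-life, translation efficiency, polyA tail
length, CAI, nTE, abundance, UTR lengths, GC content, ORF length — supplied
precomputed, as they come from heterogeneous external datasets). Missing
values are handled pairwise-complete, since coverage differs between source
datasets; any pair sharing fewer than 3 transcripts is an error naming the
pair. `clusterFeatures()` clusters the correlation matrix rows on Euclidean
distances with average linkage (UPGMA) — the distance is the conventional
choice for such heatmaps and the linkage the most common default; both are
arguments. Rows are sorted lexicographically before clustering so
equal-height merges resolve deterministically by feature name.

## The simulator and what it does (not) capture

`sampleTrueParams()` draws half-lives and abundances lognormal and
efficiencies Beta(20, 2) rescaled to (0, 1]. The lognormal half-life
marginal (median 3.6 min, log-sd 0.7) reproduces a right-skewed,
order-of-magnitude spread centred on the few-minute scale measured for
rapidly dividing yeast; abundance (median 10, log-sd 1) spans the typical
mRNA copy-number range and is drawn independently of half-life. The
Beta(20, 2) efficiency prior concentrates mass above 0.8 with a mode near
0.95, emulating an optimized capture protocol.

`simulateDecayTimecourse()` / `simulateSynthesisTimecourse()` evaluate the
noiseless channel curves on the design grid and apply per-measurement
multiplicative lognormal noise — positive, heteroscedastic signals are the
norm for RNA-seq and RT-qPCR quantification. The default grid
{0, 2, 4, 8, 16, 32} min straddles the few-minute typical half-life while
still covering transcripts beyond 30 min. The spike-in is simulated as its
own row under the same noise law, so normalization is exercised
realistically rather than assumed perfect; an optional Poisson counting
layer (`poissonScale`) is off by default. All draws are governed by the
design seed and are bit-reproducible.

Two consequences of this realism matter when interpreting simulation
benchmarks. First, each replicate's spike trajectory is shared by every
transcript, so spike noise moves all fitted half-lives coherently — exactly
as a real spike mis-measurement would — and population-level recovery
metrics fluctuate between simulated replicates. Second, dividing by the
noisy t = 0 anchor propagates that point's error into the whole series.
Under the default 5% noise, roughly 60% of fits land within 10% relative
half-life error (and essentially all within ~30%), with median efficiency
error below 0.01 per replicate. What the simulator does not emulate:
efficiency correlated with uracil content or 4TU uptake (eff is independent
per transcript), transcript-specific bead background, read-level counting
from sequencing, and any departure from steady state at the chase start.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to exercise the transcriptome-scale code paths while staying
quick: 5000 transcripts for recovery and summary statistics (the scale of a
yeast transcriptome), 1000 for the perturbation comparison, and a few
hundred elsewhere. Every stochastic step takes an explicit seed; fitting
itself is deterministic, so identical inputs give identical outputs
byte-for-byte.

## Known limitations

* The decay model assumes steady state at t = 0 and a single first-order
  pool; multi-step decay (deadenylation, decapping, exonucleolysis) is
  deliberately collapsed into one rate.
* `eff` and `Th` become weakly identified when the chase grid barely reaches
  one half-life; for very stable transcripts the efficiency baseline and
  slow decay trade off, inflating both uncertainties.
* The linear synthesis model underestimates the initial slope once the
  labeled pool saturates appreciably within the grid (about 10% at one
  half-life); it is intended for chases short relative to `Th`.
* Significance reporting follows the per-transcript convention of the assay:
  no multiple-testing correction is applied inside `pairedModelTest()`;
  `p.adjust()` can be applied to batches of p-values where appropriate.
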