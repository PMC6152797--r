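# tuChase

Transcriptome-wide mRNA half-life estimation from 4-thiouracil (4TU)
pulse-chase metabolic labeling.

## The problem

mRNA abundance is set by a balance of synthesis and decay, but decay rates
are hard to measure: classical approaches shut off transcription globally,
which itself stresses the cell and distorts the very rates being measured.
Metabolic labeling sidesteps this. 4TU added at t = 0 is incorporated into
nascent RNA, which can be biotinylated and removed on streptavidin beads;
the unlabeled flowthrough is then the pre-existing mRNA pool decaying
undisturbed, while the labeled eluate reports synthesis. Spike-in RNAs added
in constant amounts anchor the absolute scale of every timepoint.

The catch is that labeling and capture are imperfect. A fraction `1 − eff`
of new RNA escapes the pulldown and contaminates the unlabeled channel,
where at steady state it looks like a non-decaying baseline — and a plain
exponential fit mistakes that baseline for slow decay, overestimating
half-lives (badly: a true 5 min half-life reads as 8.3 min at 80%
efficiency). tuChase is built around the efficiency-modified decay model
that absorbs this into a per-transcript nuisance parameter:

    RNA(t) = eff · 2^(−t/Th) + (1 − eff)

fitted by bounded least squares after spike-in and t = 0 normalization,
with `Th` the half-life and `eff` the bulk efficiency of labeling, biotin
conjugation and separation. Synthesis rates come from the labeled channel
via the linear model `RNA(t) = ks · t + offset`.

Around that core the package provides the full analysis of a chase
experiment: fit-quality classification, transcriptome summaries (mean,
median and abundance-weighted bulk half-life, mean lifetime `Th/ln 2`,
efficiency fractions), replicate agreement, paired directional tests
contrasting the stalled-ribosome-triggered decay and translation-factor
protection models under translation inhibitors, exact paired Wilcoxon
tests, cumulative half-life distributions, codon-count fold-change
grouping, and Spearman correlation clustering of per-transcript mRNA
features. A seeded simulator generates chase experiments with known ground
truth so every stage is benchmarkable. It is intended for anyone analyzing
thiol-labeling decay time courses (yeast or otherwise) at transcript or
transcriptome scale.

## Worked example

Simulate a 2000-transcript chase (known ground truth), fit every
transcript, and summarize:

```r
library(tuChase)

params <- sampleTrueParams(2000, seed = 20)   # true Th, abundance, eff
design <- simulationDesign(noiseSigma = 0.05, channel = "decay", seed = 21)
chase  <- simulateDecayTimecourse(params, design)
chase
#> ChaseExperiment: 2000 transcripts + 1 spike-in, 6 timepoints (0, 2, 4, 8, 16, 32 min)
#> channel: decay | condition: simulated | replicate: rep1

fits <- fitTranscriptome(chase)   # spike + t0 normalization, then fitting
head(as.data.frame(fits)[, 1:5], 3)
#>   transcript_id half_life       eff r_squared status
#> 1      txp00001  9.611600 0.8645794 0.9801428     ok
#> 2      txp00002  2.638597 0.9926304 0.9995908     ok
#> 3      txp00003 11.589574 0.8912525 0.9754692     ok
unlist(metadata(fits)$statusCounts)
#>             ok       poor_fit          unfit low_expression
#>           1997              3              0              0

round(unlist(summarizeHalfLives(fits)), 3)
#>          n_total             n_ok   mean_half_life median_half_life
#>         2000.000         1997.000            5.762            4.238
#>    mean_lifetime  frac_eff_gt_090  frac_eff_gt_080   frac_r2_gt_095
#>            8.312            0.682            0.927            0.925

round(bulkHalfLife(chase), 2)   # abundance-weighted pool half-life
#> [1] 3.9
```

Each fit row gives the transcript's half-life in minutes, its capture
efficiency, the R² of the model fit and a status (`ok` / `poor_fit` /
`unfit` / `low_expression`). The summary reports statistics over `ok` fits:
here a 5.8 min mean (4.2 min median) half-life and, e.g., 68% of
transcripts captured with > 90% efficiency. Note the fitted population
tilts slightly long at this seed because the spike-in's own measurement
noise is shared by every transcript — exactly as in a real experiment.

Why the efficiency term matters — naive exponential fits on noiseless data
generated with imperfect capture:

```r
inefficiencyBias()
#>   eff true_half_life naive_half_life         bias
#> 1 1.0              5        5.000000 9.954775e-10
#> 2 0.9              5        6.270289 1.270289e+00
#> 3 0.8              5        8.258105 3.258105e+00
#> 4 0.6              5       15.804676 1.080468e+01
```

Real data enter through `readCounts()` (TSV of transcript × `t<minutes>`
columns with a designated spike-in row); perturbation comparisons use
`pairedModelTest()`, `wilcoxonPaired()`, `halfLifeEcdf()`,
`crossConditionSpearman()` and `foldChangeByCount()`; feature analysis uses
`spearmanMatrix()` and `clusterFeatures()`. See the methods vignette
(`vignettes/tuChase-methods.Rmd`) for the models, defaults and their
rationale.

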