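# spikenorm

Spike-in control based normalization (SCN) for miRNA microarray raw data,
with quality-control metrics, detection calls, and dose-response
differential expression.

## The problem

miRNA arrays carry few probes compared with mRNA arrays, and real
treatments can shift the expression of *most* miRNAs in one direction (a
global decrease). Normalization methods that equalize whole intensity
distributions across arrays — quantile normalization above all — then
erase part of the biology they are supposed to preserve. Spike-in
controls offer a way out: synthetic RNAs added at the *same* concentration
to every sample should measure identically on every array, so any
deviation of a spike-in probe set from its across-array mean is a direct
readout of array-specific technical bias, independent of the biology.

## The method

Let `E_jk` be the log2 intensity of spike-in probe set `j` on array `k`
(probe sets are median-summarized over their replicate probes), and
`E_j^mean` its mean over arrays. SCN models

```
E_jk = E_j^mean + dE_jk + eps_jk
```

and estimates the correction `dE_jk` in two steps:

1. **Shared deviation (multi-array step).** Each centered row
   `E_jk − E_j^mean` is divided by its Euclidean norm over arrays, giving
   `U_jk`; the mean over spike sets, `U_k^mean`, is the deviation pattern
   shared by all spike sets (assumption A1: their pairwise Pearson
   correlations are high). Scaling back by each row's norm gives the
   rank-1 correction matrix `dE_jk = ‖E_j − E_j^mean‖ · U_k^mean`, whose
   row norms carry the intensity dependence.
2. **Correction function.** Per array, the points
   `(E_j^mean, dE_jk)` are extended to the full intensity range of the
   data (a stabilization knot at the dataset minimum; linear
   extrapolation through the two highest spike sets at the top),
   LOWESS-smoothed (span 0.4), and interpolated piecewise-linearly into
   `dE(x, k)`. Normalized data are `E − dE(E, k)`.

Applicability is checked before any correction: A1 (median off-diagonal
spike correlation ≥ 0.5), A2 (within-set probe SD smaller than the gap
between spike levels), A3 (spike levels cover the miRNA intensity range up
to 2 log2 units of overhang). If any check fails, MEDIAN normalization is
applied instead and the fact is reported — for a constant correction
function SCN *is* MEDIAN.

The package also provides: MEDIAN and quantile baselines; Exiqon
(1.5 × array median, ≥ 2 of 4 probes) and Wilcoxon rank-sum detection
calls; the four CV quality metrics (`CVwithin`, `CVbetween`, `CVtreat`,
`relativeCVspike`); a dose-response linear model with empirical-Bayes
moderated t-statistics; comparative-Ct RT-qPCR processing with
leave-one-out Spearman confidence intervals; and a synthetic-experiment
simulator (16 arrays, 4 dose groups, 600 miRNA probe sets × 4 probes, 10
spike-in sets × 48 probes spanning log2 4–14) with recorded ground truth.

## Worked example

```r
library(spikenorm)
sim <- simulate_experiment(simulation_config(seed = 7))
res <- scn_normalize(sim$data, sim$design)
print(res)
#> SCN normalization result: method used = scn
#>   A1 pass (median off-diag corr 0.995, threshold 0.50)
#>   A2 pass (max within-set SD 0.119, min gap 1.084)
#>   A3 pass (covered fraction 1.00)
#>   fallback used: FALSE

de <- fit_dose_response(res$probesets, sim$design)
head(de[order(de$p.value), c("probe_set", "slope", "t", "p.value", "fdr")], 5)
#>     probe_set slope     t  p.value      fdr
#> 441  mir_0441 -1.58 -30.5 8.06e-20 2.68e-17
#> 387  mir_0387 -1.83 -30.4 8.78e-20 2.68e-17
#> 98   mir_0098  2.02  28.3 4.10e-19 6.57e-17
#> 89   mir_0089 -1.72 -28.3 4.31e-19 6.57e-17
#> 466  mir_0466 -1.93 -27.4 8.58e-19 9.31e-17
```

The assumption report says the spike-in deviations were coherent enough
(A1), well separated in intensity (A2) and wide enough in coverage (A3)
for the correction to be built; no fallback was needed. The top
dose-response hits recover the simulator's true slopes closely (e.g.
`mir_0441`: estimated −1.58 vs true −1.60; slopes are log2 change per
unit normalized dose, dose scaled to max = 1). On the same run the QC
medians are `CVwithin ≈ 0.0089`, `CVbetween ≈ 0.0084` and
`relativeCVspike ≈ 0.056` — the spike-in (technical) variability sits at
the very bottom of the biological-replicate CV range, as it should after
a spike-in-calibrated normalization.

## Command line

```sh
Rscript inst/cli/spikenorm.R run --method scn --out out_dir --seed 7
Rscript inst/cli/spikenorm.R simulate --out fixture_dir --seed 7
Rscript inst/cli/spikenorm.R run --input fixture_dir --method median --out out2
```

(after installation, the script lives at
`system.file("cli", "spikenorm.R", package = "spikenorm")`). Subcommands:
`simulate`, `normalize`, `qc`, `de`, `run`; `--config FILE` accepts a
JSON (or YAML) pipeline configuration. All outputs are plain TSV/JSON and
runs are byte-identical given the same config and seed.

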