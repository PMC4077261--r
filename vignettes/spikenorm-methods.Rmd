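---
title: "Spike-in calibrated normalization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated normalization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikenorm)
```

## The model

Raw probe intensities are kept on the log2 scale throughout (importers
floor linear values at 1 before the transform, so no entry is
non-finite). Probe sets are summarized by the per-array median of their
replicate probes; quality flags are deliberately ignored at
summarization — they feed only the detection calls.

For the spike-in probe sets, whose RNA is added at identical
concentration to every sample, the summarized matrix is decomposed as

$$E^{(S)}_{jk} = E^{(S,\mathrm{mean})}_j + \Delta E^{(S)}_{jk} + \varepsilon_{jk},$$

where the row mean over arrays estimates the true (sample-independent)
spike intensity, $\Delta E^{(S)}_{jk}$ is the systematic array-specific
deviation to be corrected, and $\varepsilon$ is noise. The correction is
estimated by centering each row, dividing by its Euclidean norm over
arrays ($U_{jk}$), averaging $U$ over spike sets into the shared pattern
$U^{(\mathrm{mean})}_k$, and scaling back per row:
$\Delta E^{(S)}_{jk} = \lVert E^{(S)}_{j\cdot} -
E^{(S,\mathrm{mean})}_j\rVert_2 \, U^{(\mathrm{mean})}_k$.

Two consequences are used as invariants in the test suite: the
correction matrix is exactly rank 1 (an outer product), and every row
sums to zero over arrays (each $U$ row is centered, hence so is their
mean). When the deviations truly share one array pattern with equal-sign
row coefficients and no noise, the residuals vanish identically.

**Norm reading.** The source notation for the scaling factor is an
absolute value $|E^{(S)}_{jk} - E^{(S,\mathrm{mean})}_j|$, but a
per-element absolute value would collapse every $U$ entry to $\pm 1$ and
destroy the intensity dependence the method relies on; since the factor
is described as depending on the probe set $j$ (not on $k$), it is read
as the Euclidean norm of the centered row. This is the only reading
under which the back-transform reproduces the deviations of a coherent
rank-1 signal exactly.

## Applicability checks

* **A1 (shared variance).** Pearson correlations between spike-set rows;
  pass when the *median* off-diagonal value is at least 0.5. Requiring
  the median rather than *all* off-diagonals above threshold makes one
  noisy spike set (low-intensity sets are noisier in practice) unable to
  veto an otherwise coherent panel; both mean and median are reported.
  Constant rows get correlation 0 and a recorded warning.
* **A2 (well-defined spike intensities).** Per spike set, the probe SD
  pooled over arrays (root mean of per-array variances) must be smaller
  than the smallest gap between consecutive sorted spike-set means.
* **A3 (coverage).** The spike-set means must cover the 5th–95th
  percentile band of the miRNA probe-set intensities up to 2 log2 units
  of overhang per side. The source states no number, only that a
  "limited extrapolation" is tolerable; the band and overhang are
  explicit, configurable parameters (`band_probs`, `max_extrapolation`),
  and the boundary comparison is inclusive.

If any check fails — or the data carry fewer than 2 spike-in sets or 3
arrays — MEDIAN normalization is applied and `fallback_used` is set. The
fallback's output is bitwise identical to calling `median_normalize()`
directly.

## The correction function

Per array, knots start at $(E^{(S,\mathrm{mean})}_j, \Delta
E^{(S)}_{jk})$ and are extended to the dataset's full intensity range:

1. a stabilization knot at the dataset minimum carrying the lowest
   spike set's correction;
2. extrapolation knots at every integer intensity between the highest
   spike mean and the dataset maximum (plus the maximum itself), on the
   straight line through the two highest spike points. Anchors are taken
   at probe-*set* level (two highest mean intensities, stable sort by
   (mean, label) on ties) although the source mentions "probes": the
   whole construction operates on probe sets elsewhere, and set-level
   anchors are more stable;
3. LOWESS smoothing of the knot set — tricube-weighted local *linear*
   regression with span 0.4 (the stated smoothing parameter) and 3
   robustifying iterations (`stats::lowess`), evaluated at the knot
   positions;
4. piecewise-linear interpolation through the smoothed knots, clamped to
   the end knots outside their range.

The order stabilize → extrapolate → smooth → interpolate follows the
stated procedure verbatim. Corrections are *computed* at probe-set level
and *applied* at any level by evaluating $\Delta E(x,k)$ at each entry's
own intensity, so probe-level data inherit the set-level function.

Because the channel of a common-reference dual-channel design is
imported alone ("pseudo-single-channel"), no channel term appears in the
correction; the importer simply never reads the reference channel.

## Numerical choices and degenerate inputs

* Sample SD ($n-1$) everywhere, including all CV metrics and their test
  oracles.
* Quartiles and percentile bands use linear interpolation (R type 7);
  whisker fences are $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
  1.5\,\mathrm{IQR}]$ and the whisker endpoints are the extreme
  *observed* values inside the fences, which is why the quartile
  convention is load-bearing and pinned.
* Spike rows constant across arrays get zero norm, $U = 0$, zero
  correction.
* A single-array dataset is rejected at construction (the method is
  multi-array by definition); quantile normalization requires ≥ 2
  arrays; a zero-width CVbetween whisker range is an error for
  `relativeCVspike`.
* `CVtreat` divides by $(N_l + N_{\mathrm{control}})$ — as printed in
  its definition, not the conventional pooled-SE form of an inverse t —
  and uses the absolute group-mean difference so the metric is a
  nonnegative dispersion measure; zero differences give `Inf`, excluded
  from summaries. The discrepancy with a literal inverse t-statistic is
  deliberate fidelity, not an oversight.
* Exiqon detection thresholds are applied on the linear scale
  (`2^E > 1.5 ×` array median): a 1.5× multiple of a log2 value would
  depend on the unit of the raw scanner counts. Any nonzero ImaGene flag
  counts as bad quality; both choices are configurable. "Absent"
  exclusions are per-entry for `CVwithin`; group-level metrics mask a
  (set, group) value when any member entry (including the control group,
  for `CVtreat`) is absent.
* The rank-sum detection test is exact: the tie-free path uses the exact
  Wilcoxon distribution and ties are handled by full midrank permutation
  enumeration up to a budget, beyond which a tie-corrected normal
  approximation with continuity correction applies.
* Variance moderation follows the standard empirical-Bayes scheme:
  method-of-moments on $\log s^2_j$ with an inverse-trigamma Newton
  solve; non-positive excess dispersion yields $d_0 = \infty$ with the
  arithmetic-mean variance (the unbiased estimate under the scaled
  $\chi^2$ model); exact zero variances are offset to $10^{-5}\times$
  the median before taking logs; the total df is capped at the pooled
  residual df of the dataset. `prior_df = 0` recovers the ordinary t
  exactly — used as a limit test.
* The "normalized dose vector" is taken as dose divided by the maximum
  dose (so slopes are log2 change over the full dose range); ordinal
  coding (0, 1, 2, …) is available since the source does not define its
  normalization.
* Comparative-Ct sign: the printed formula ("high" minus "sham") is
  mirrored by default so that a *higher* treated Ct (less miRNA) yields a
  *negative* value, matching the biological reading of down-regulation;
  `sign_convention = "as_printed"` reproduces the literal formula.
  BH-FDR columns in the DE output are an addition, labeled as such.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates the stated design (16 arrays, 4 × 4,
doses 0/75/150/300; 600 miRNA sets × 4 probes; 10 spike sets × 48 probes
over log2 4–14) with:

* per-probe affinity offsets (SD 0.1), probe noise (SD 0.05),
  biological replicate noise per miRNA set and array (SD 0.1) — values
  chosen once as realistic for a good-quality miRNA array, consistent
  with within-array CVs of order 1%;
* an array bias $b_k(x) = a_k\, s(x)$ applied to *all* probes as a
  function of their noise-free expected intensity, with a shared cubic
  smoothstep shape $s(x) = 0.3 + 0.7(3t^2 - 2t^3)$ over the spike range
  and zero-sum amplitudes scaled to `bias_amplitude` (default 0.5). The
  bias is separable with a sign-constant shape because that is the class
  of deviation a rank-1 multi-array correction is built to capture; the
  0.3 floor keeps the bias non-degenerate at low intensity, where real
  scanner biases do not vanish. The zero-sum constraint across arrays
  makes the truth identifiable (the estimated corrections are zero-sum
  by construction);
* a `"constant"` bias model using the symmetric ladder
  `seq(-A, A, length = K)`: zero-sum *and* zero-median for even K, which
  is what makes the SCN≡MEDIAN degeneracy exact (SCN centers by the
  across-array mean, MEDIAN re-centers to the grand median — the two
  agree entrywise only when the offsets' mean equals their median);
* optional incoherent per-(spike set, array) deviations
  (`spike_deviation_sd`) to violate A1 on purpose, and a
  `global_decrease` mode in which 90% of differential slopes are
  negative and a further 60% of all sets receive a small negative slope
  (0.1–0.5), emulating a dataset-wide decrease.

Biases that the simulator does **not** emulate: spatial artifacts,
dye chemistry, probe-sequence-specific cross-hybridization between
spike-ins and biological RNA, and non-separable (rank ≥ 2) intensity
biases. A green recovery test therefore establishes that the
implementation extracts what the model class can express — not that the
model class captures every real-world bias; on real data the residual
spike variance after correction is the honest diagnostic.

## Verification design

Every spec-level example value is either asserted directly (closed-form
arithmetic), or computed by an independent oracle frozen into the test:
piecewise-linear interpolation is checked against a loop-written
interpolator, rank-sum p-values against full `combn` enumeration,
quantile normalization against the limma reference implementation,
moderated t against `limma::eBayes`, and all CV metrics against
formula-literal recomputations.

Two properties deserve a note:

* **Idempotence.** On a noiseless constant-bias dataset a second SCN
  pass changes nothing (to 1e-8). For smooth biases the second pass is
  only *much smaller* than the first, not zero: LOWESS smoothing leaves
  a curvature-proportional remnant at the knots, which the second pass
  picks up. The test asserts the strict ordering.
* **DE recovery.** The Spearman comparison of true vs estimated slopes
  is computed over the truly differential sets: with 90% of sets at
  exactly slope 0, a rank correlation over all sets would be dominated
  by the tied null block and measure nothing about recovery. The
  "sign-distorted fraction" used in the SCN-vs-quantile comparison is
  the fraction of sets called significant (moderated p < 0.05) whose
  estimated slope sign differs from the true sign, with true slope 0
  counting as a mismatch — under a global decrease, quantile
  normalization pushes the whole distribution up and inflates exactly
  this quantity.

## Known limitations

* The correction shares one knot grid in x (the spike-set means) across
  arrays; arrays whose bias is strong enough to shift spike intensities
  across each other are outside the model.
* Moderated-t hyperparameter estimation assumes a common residual df
  across probe sets (true for the single-regressor dose model on a
  complete matrix).
* The ImaGene reader implements a minimal documented dialect (a
  `Begin Raw Data`/`End Raw Data` block with `Gene ID`, `Signal Median`,
  `Background Median`, `Flag`), not every export variant of the scanner
  software; the generic TSV importer covers everything else.
* Background handling is plain subtraction with a floor — convolution
  model background correction (normexp) is out of scope.
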