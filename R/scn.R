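#' Extract the spike-in control sub-matrices
#'
#' Pulls out the spike-in probe-set matrix `E^(S)_jk`, its row means
#' `E^(S,mean)_j` (the multi-array estimate of the true spiked
#' concentrations, constant across samples by design), and the underlying
#' spike-in probe-level matrix used by the A2 check.
#'
#' @param psd a [probe_set_data()] object (median-summarized).
#' @param pld the originating [probe_level_data()] object.
#' @return an object of class `SpikeInMatrix` with elements `values`,
#'   `row_means`, `probe_level`, `probe_set_of_probe`.
#' @export
extract_spikein <- function(psd, pld) {
  ann <- aligned_annotation(pld)
  spike_sets <- unique(ann$probe_set[ann$probe_class == "spikein"])
  if (length(spike_sets) < 2)
    stop("SCN requires at least 2 spike-in probe sets; found ",
         length(spike_sets))
  values <- psd$intensities[spike_sets, , drop = FALSE]
  probes <- ann$probe_class == "spikein"
  structure(
    list(values = values,
         row_means = rowMeans(values),
         probe_level = pld$intensities[probes, , drop = FALSE],
         probe_set_of_probe = stats::setNames(ann$probe_set[probes],
                                              ann$probe[probes])),
    class = "SpikeInMatrix")
}

#' Check assumption A1: shared variance among spike-in deviations
#'
#' Computes the Pearson correlation matrix between the rows of the spike-in
#' probe-set matrix. Off-diagonal correlations close to 1 mean the
#' array-to-array deviations of the different spike sets share a common
#' sample dependence, which is what the first step of SCN extracts. The
#' check passes when the median off-diagonal correlation reaches
#' `threshold` (the mean is reported alongside).
#'
#' @param sm a [extract_spikein()] result.
#' @param threshold pass threshold on the median off-diagonal correlation.
#' @return list with elements `pass`, `median_offdiag`, `mean_offdiag`,
#'   `threshold`, `corr`, `warnings`.
#' @export
check_assumption_a1 <- function(sm, threshold = 0.5) {
  E <- sm$values
  if (ncol(E) < 3)
    stop("assumption A1 needs at least 3 arrays for Pearson correlations")
  warn <- character(0)
  sds <- apply(E, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(E)))
  if (any(sds == 0)) {
    const <- rownames(E)[sds == 0]
    warn <- paste("constant spike-in row(s), correlations set to 0:",
                  paste(const, collapse = ", "))
    C[const, ] <- 0
    C[, const] <- 0
    diag(C) <- 1
  }
  off <- C[lower.tri(C)]
  list(pass = stats::median(off) >= threshold,
       median_offdiag = stats::median(off),
       mean_offdiag = mean(off),
       threshold = threshold, corr = C, warnings = warn)
}

#' Check assumption A2: spike-in probe sets map to well-separated intensities
#'
#' For each spike set the within-set probe standard deviation (pooled over
#' arrays, i.e. the root mean of the per-array probe variances) must be
#' smaller than the smallest gap between consecutive sorted probe-set mean
#' intensities, so that each set defines a distinct intensity knot.
#'
#' @param sm a [extract_spikein()] result.
#' @return list with elements `pass`, `within_sd` (per set), `min_gap`.
#' @export
check_assumption_a2 <- function(sm) {
  sets <- rownames(sm$values)
  within_sd <- vapply(sets, function(j) {
    probes <- names(sm$probe_set_of_probe)[sm$probe_set_of_probe == j]
    sub <- sm$probe_level[probes, , drop = FALSE]
    if (nrow(sub) < 2) return(0)
    sqrt(mean(apply(sub, 2, stats::var)))
  }, 0)
  gaps <- diff(sort(sm$row_means))
  min_gap <- if (length(gaps)) min(gaps) else 0
  list(pass = all(within_sd < min_gap), within_sd = within_sd,
       min_gap = min_gap)
}

#' Check assumption A3: spike-ins cover the miRNA intensity range
#'
#' The spike-set mean intensities must cover the central band (5th to 95th
#' percentile by default) of all miRNA probe-set intensities, allowing at
#' most `max_extrapolation` log2 units of overhang on each side (the method
#' tolerates a limited extrapolation of the correction function).
#'
#' @param sm a [extract_spikein()] result.
#' @param full the full [probe_set_data()] (miRNA sets are selected by
#'   their probe class).
#' @param max_extrapolation allowed overhang per side, log2 units.
#' @param band_probs percentile band of the miRNA intensity distribution.
#' @return list with elements `pass`, `covered_fraction`, `spike_range`,
#'   `mirna_band`, `max_extrapolation`.
#' @export
check_assumption_a3 <- function(sm, full, max_extrapolation = 2,
                                band_probs = c(0.05, 0.95)) {
  is_mirna <- if (is.null(full$probe_class)) {
    !rownames(full$intensities) %in% rownames(sm$values)
  } else full$probe_class == "mirna"
  mirna <- full$intensities[is_mirna, , drop = FALSE]
  band <- stats::quantile(mirna, band_probs, names = FALSE, type = 7)
  spike_range <- range(sm$row_means)
  covered <- max(0, min(spike_range[2], band[2]) - max(spike_range[1], band[1]))
  list(pass = band[1] >= spike_range[1] - max_extrapolation &&
         band[2] <= spike_range[2] + max_extrapolation,
       covered_fraction = covered / (band[2] - band[1]),
       spike_range = spike_range, mirna_band = band,
       max_extrapolation = max_extrapolation)
}

#' First step of SCN: spike-in normalization corrections
#'
#' Decomposes the spike-in probe-set matrix as
#' `E^(S)_jk = E^(S,mean)_j + dE^(S)_jk + eps_jk`. Each centered row is
#' divided by its Euclidean norm over arrays (`U_jk`); averaging `U` over
#' spike sets isolates the shared, sample-specific deviation `U^(mean)_k`,
#' which is scaled back per set by the row norm to give the corrections
#' `dE^(S)_jk`. The row norm carries the intensity dependence: sets whose
#' deviations are larger receive proportionally larger corrections.
#'
#' Rows with a centered norm below 1e-12 (constant across arrays) get
#' `U = 0` and a zero correction.
#'
#' @param sm a [extract_spikein()] result.
#' @return an object of class `SpikeInCorrections` with elements `U`,
#'   `u_mean`, `row_norms`, `delta_s` (the corrections `dE^(S)_jk`),
#'   `residuals` (`eps_jk`) and `corr` (the row correlation matrix).
#' @export
compute_spikein_corrections <- function(sm) {
  E <- sm$values
  dev <- E - rowMeans(E)
  row_norms <- sqrt(rowSums(dev^2))
  U <- dev / ifelse(row_norms < 1e-12, Inf, row_norms)
  u_mean <- colMeans(U)
  delta_s <- outer(row_norms, u_mean)
  dimnames(delta_s) <- dimnames(E)
  sds <- apply(E, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(E)))
  C[sds == 0, ] <- 0
  C[, sds == 0] <- 0
  diag(C) <- 1
  structure(
    list(U = U, u_mean = u_mean, row_norms = row_norms,
         delta_s = delta_s, residuals = dev - delta_s, corr = C),
    class = "SpikeInCorrections")
}

#' Second step of SCN: build the per-array correction function
#'
#' Extends the discrete spike-set corrections `dE^(S)_jk` into a continuous
#' correction function `dE(x, k)` defined on the whole intensity range of
#' the dataset, in four stages applied per array:
#'
#' 1. *Stabilization at low intensities*: if the dataset minimum lies below
#'    the lowest spike knot, a knot is prepended there carrying the
#'    correction of the closest (lowest-intensity) spike set.
#' 2. *Linear extrapolation at high intensities*: if the dataset maximum
#'    exceeds the highest spike knot, knots are appended at every integer
#'    intensity in between plus the maximum itself, on the straight line
#'    through the two highest-intensity spike-set points.
#' 3. *Smoothing*: LOWESS (tricube local linear, `lowess_frac`, `iter`
#'    robustifying iterations) over the knot set, evaluated at the knots.
#' 4. *Interpolation*: the final function interpolates the smoothed knots
#'    piecewise-linearly and clamps to the end knots outside their range.
#'
#' @param sc a [compute_spikein_corrections()] result.
#' @param sm the matching [extract_spikein()] result (provides the knot
#'   x positions `E^(S,mean)_j`).
#' @param full the dataset the function must cover: a [probe_level_data()]
#'   or [probe_set_data()] object (its overall intensity range defines the
#'   stabilization/extrapolation targets).
#' @param lowess_frac LOWESS smoother span.
#' @param iter LOWESS robustifying iterations.
#' @return an object of class `CorrectionFunction`: per-array knot tables
#'   `(x, delta, provenance)` with a piecewise-linear, clamped evaluation
#'   rule (see [predict.CorrectionFunction()]).
#' @export
build_correction_function <- function(sc, sm, full, lowess_frac = 0.4,
                                      iter = 3) {
  if (nrow(sm$values) < 2)
    stop("fewer than 2 spike-in sets: the high-intensity extrapolation ",
         "line is undefined; use MEDIAN normalization instead")
  E_full <- if (is.matrix(full)) full else full$intensities
  emin <- min(E_full)
  emax <- max(E_full)
  ord <- order(sm$row_means, names(sm$row_means))
  x0 <- unname(sm$row_means[ord])
  arrays <- colnames(sm$values)
  knots <- lapply(arrays, function(k) {
    y0 <- unname(sc$delta_s[ord, k])
    x <- x0; y <- y0
    prov <- rep("spike", length(x))
    if (emin < x[1]) {                       # stabilization at low intensity
      x <- c(emin, x); y <- c(y[1], y)
      prov <- c("stabilize", prov)
    }
    n <- length(x0)
    if (emax > x0[n]) {                      # linear extrapolation, high end
      slope <- (y0[n] - y0[n - 1]) / (x0[n] - x0[n - 1])
      ints <- seq_len(floor(emax))
      ints <- ints[ints > x0[n] & ints <= emax]
      xe <- unique(c(ints, emax))
      ye <- y0[n] + slope * (xe - x0[n])
      x <- c(x, xe); y <- c(y, ye)
      prov <- c(prov, rep("extrapolate", length(xe)))
    }
    # collapse duplicate x (can only arise from coincident knots)
    if (anyDuplicated(x)) {
      ux <- unique(x)
      y <- vapply(ux, function(v) mean(y[x == v]), 0)
      prov <- prov[!duplicated(x)]
      x <- ux
    }
    sm_fit <- stats::lowess(x, y, f = lowess_frac, iter = iter)
    data.frame(x = sm_fit$x, delta = sm_fit$y, provenance = prov,
               raw_delta = y, stringsAsFactors = FALSE)
  })
  names(knots) <- arrays
  structure(list(knots = knots, arrays = arrays,
                 lowess_frac = lowess_frac, iter = iter,
                 range = c(emin, emax)),
            class = "CorrectionFunction")
}

#' Evaluate a correction function
#'
#' Piecewise-linear interpolation through the smoothed knots of one array,
#' clamped to the end-knot values outside the knot range.
#'
#' @param object a [build_correction_function()] result.
#' @param x numeric vector of log2 intensities.
#' @param array array label.
#' @param ... ignored.
#' @return numeric vector of corrections `dE(x, k)`.
#' @export
predict.CorrectionFunction <- function(object, x, array, ...) {
  if (!array %in% object$arrays)
    stop("array label absent from the correction function: ", array)
  kn <- object$knots[[array]]
  stats::approx(kn$x, kn$delta, xout = x, rule = 2, ties = "ordered")$y
}

#' Serialize correction-function knots to TSV
#' @param cf a [build_correction_function()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_correction_tsv <- function(cf, path) {
  tab <- do.call(rbind, lapply(cf$arrays, function(k)
    cbind(array = k, cf$knots[[k]])))
  utils::write.table(
    format(tab, digits = 15, scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a correction function to probe- or probe-set-level data
#'
#' Every entry is replaced by `E - dE(E, k)`: the correction is evaluated
#' at the entry's own intensity, so probe-level application inherits the
#' probe-set-level correction function evaluated at each probe's intensity.
#'
#' @param data a [probe_level_data()] or [probe_set_data()] object.
#' @param cf a [build_correction_function()] result.
#' @return object of the same class with corrected intensities.
#' @export
apply_correction <- function(data, cf) {
  E <- data$intensities
  miss <- setdiff(colnames(E), cf$arrays)
  if (length(miss))
    stop("array label(s) absent from the correction function: ",
         paste(miss, collapse = ", "))
  for (k in colnames(E))
    E[, k] <- E[, k] - predict(cf, E[, k], k)
  data$intensities <- E
  data
}

#' Spike-in controls based normalization (SCN) with MEDIAN fallback
#'
#' Full orchestration: median summarization, spike-in extraction, the
#' applicability checks A1-A3, the two-step construction of the correction
#' function, and its application at both probe-set and probe level. If any
#' check fails (or the data carry fewer than 2 spike-in sets, or fewer than
#' 3 arrays), the method falls back to MEDIAN normalization and records the
#' fact in the assumption report.
#'
#' @param pld a [probe_level_data()] object.
#' @param design optional [experiment_design()] (not used by the
#'   normalization itself; validated against the arrays when given).
#' @param a1_threshold pass threshold for [check_assumption_a1()].
#' @param max_extrapolation overhang allowed by [check_assumption_a3()].
#' @param lowess_frac LOWESS span of [build_correction_function()].
#' @return an object of class `scn_result`: list with `probesets`
#'   (normalized [probe_set_data()]), `probelevel` (normalized
#'   [probe_level_data()]), `report` (assumption report with elements
#'   `a1`, `a2`, `a3`, `fallback_used`), `correction`
#'   (a `CorrectionFunction`, or `NULL` on fallback), `corrections`
#'   (the `SpikeInCorrections`, or `NULL`), `method_used`.
#' @export
scn_normalize <- function(pld, design = NULL, a1_threshold = 0.5,
                          max_extrapolation = 2, lowess_frac = 0.4) {
  if (!is.null(design)) check_design_covers(design, colnames(pld$intensities))
  psd <- summarize_probesets(pld)
  ann <- aligned_annotation(pld)
  n_spike <- length(unique(ann$probe_set[ann$probe_class == "spikein"]))
  fallback <- function(report) {
    warning("SCN assumptions not met; falling back to MEDIAN normalization",
            call. = FALSE)
    structure(list(probesets = median_normalize(psd),
                   probelevel = median_normalize(pld),
                   report = report, correction = NULL, corrections = NULL,
                   method_used = "median"),
              class = "scn_result")
  }
  if (n_spike < 2 || ncol(pld$intensities) < 3) {
    report <- list(a1 = NULL, a2 = NULL, a3 = NULL, fallback_used = TRUE,
                   reason = if (n_spike < 2) "fewer than 2 spike-in sets"
                            else "fewer than 3 arrays")
    return(fallback(report))
  }
  sm <- extract_spikein(psd, pld)
  a1 <- check_assumption_a1(sm, threshold = a1_threshold)
  a2 <- check_assumption_a2(sm)
  a3 <- check_assumption_a3(sm, psd, max_extrapolation = max_extrapolation)
  report <- list(a1 = a1, a2 = a2, a3 = a3,
                 fallback_used = !(a1$pass && a2$pass && a3$pass))
  if (report$fallback_used) return(fallback(report))
  sc <- compute_spikein_corrections(sm)
  cf <- build_correction_function(sc, sm, pld, lowess_frac = lowess_frac)
  structure(list(probesets = apply_correction(psd, cf),
                 probelevel = apply_correction(pld, cf),
                 report = report, correction = cf, corrections = sc,
                 method_used = "scn"),
            class = "scn_result")
}

#' @export
print.scn_result <- function(x, ...) {
  cat("SCN normalization result: method used =", x$method_used, "\n")
  r <- x$report
  if (!is.null(r$a1))
    cat(sprintf("  A1 %s (median off-diag corr %.3f, threshold %.2f)\n",
                if (r$a1$pass) "pass" else "FAIL",
                r$a1$median_offdiag, r$a1$threshold))
  if (!is.null(r$a2))
    cat(sprintf("  A2 %s (max within-set SD %.3f, min gap %.3f)\n",
                if (r$a2$pass) "pass" else "FAIL",
                max(r$a2$within_sd), r$a2$min_gap))
  if (!is.null(r$a3))
    cat(sprintf("  A3 %s (covered fraction %.2f)\n",
                if (r$a3$pass) "pass" else "FAIL", r$a3$covered_fraction))
  cat("  fallback used:", r$fallback_used, "\n")
  invisible(x)
}
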