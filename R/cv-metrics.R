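#' Within-array coefficient of variation
#'
#' For each probe set and array, the dispersion of the log2 intensities of
#' the set's replicate probes: sample SD over probes divided by their mean.
#' Entries whose detection call is "absent" (when `detection` is given),
#' whose set has fewer than 2 probes, or whose probe mean is 0 are marked
#' excluded; values are still computed where defined.
#'
#' @param pld a [probe_level_data()] object (raw, log2).
#' @param detection optional logical present/absent matrix
#'   (probe set x array) as returned by the detection-call functions.
#' @return list with `values` (probe set x array matrix of CVs) and
#'   `excluded` (logical mask, `TRUE` = excluded from distribution
#'   summaries).
#' @export
cv_within <- function(pld, detection = NULL) {
  ann <- aligned_annotation(pld)
  sets <- unique(ann$probe_set)
  idx <- split(seq_len(nrow(pld$intensities)), ann$probe_set)[sets]
  K <- ncol(pld$intensities)
  values <- t(vapply(idx, function(i) {
    sub <- pld$intensities[i, , drop = FALSE]
    if (nrow(sub) < 2) return(rep(NA_real_, K))
    apply(sub, 2, stats::sd) / colMeans(sub)
  }, numeric(K)))
  colnames(values) <- colnames(pld$intensities)
  values[is.infinite(values)] <- NA_real_
  excluded <- is.na(values)
  if (any(excluded & t(vapply(idx, function(i) rep(length(i) >= 2, K),
                              logical(K)))))
    warning("some CVwithin values are undefined (zero probe mean); ",
            "marked excluded", call. = FALSE)
  if (!is.null(detection))
    excluded <- excluded | !detection[rownames(values), , drop = FALSE]
  list(values = values, excluded = excluded)
}

#' Between-array (biological replicate) coefficient of variation
#'
#' For each probe set and treatment group with at least 2 arrays, the
#' sample SD over the group's arrays divided by the group mean, computed on
#' normalized probe-set intensities. The pooled values over all groups form
#' the CVbetween distribution whose whisker range calibrates
#' [cv_spike_relative()].
#'
#' @param psd normalized [probe_set_data()].
#' @param design an [experiment_design()] object.
#' @param detection optional present/absent matrix; a (set, group) value is
#'   excluded when any member entry of the group is absent.
#' @return list with `values` (probe set x group matrix), `excluded` mask.
#' @export
cv_between <- function(psd, design, detection = NULL) {
  E <- psd$intensities
  check_design_covers(design, colnames(E))
  grp <- design$group_of[colnames(E)]
  counts <- table(factor(grp, levels = names(design$dose_of)))
  groups <- names(design$dose_of)[counts >= 2]
  values <- sapply(groups, function(l) {
    sub <- E[, grp == l, drop = FALSE]
    apply(sub, 1, stats::sd) / rowMeans(sub)
  })
  values <- matrix(values, nrow = nrow(E),
                   dimnames = list(rownames(E), groups))
  values[is.infinite(values)] <- NA_real_
  excluded <- is.na(values)
  if (!is.null(detection)) {
    for (l in groups)
      excluded[, l] <- excluded[, l] |
        rowSums(!detection[rownames(E), grp == l, drop = FALSE]) > 0
  }
  list(values = values, excluded = excluded)
}

#' Treatment-induced coefficient of variation
#'
#' A residual-noise-to-signal ratio per probe set and treated group,
#' similar to the inverse of the t-statistic of the treated-vs-control
#' comparison. With `R_jk = E_jk - mean(E_j over k's own group)` for the
#' arrays of treated group `l` and of the control group:
#' `CVtreat_jl = sqrt(sum_k R_jk^2) / (N_l + N_control) /
#'  |mean_l(E_j) - mean_control(E_j)|`
#' (the `1/(N_l + N_control)` prefactor is the definition as printed, not a
#' conventional pooled standard error; the absolute value in the
#' denominator makes the metric a nonnegative dispersion measure). A zero
#' group-mean difference gives `Inf`, excluded from summaries.
#'
#' @param psd normalized [probe_set_data()].
#' @param design an [experiment_design()] object.
#' @param detection optional present/absent matrix; a (set, group) value is
#'   excluded when any member entry of the treated or control group is
#'   absent.
#' @return list with `values` (probe set x treated group), `residuals`
#'   (probe set x array matrix of `R_jk`), `excluded` mask.
#' @export
cv_treat <- function(psd, design, detection = NULL) {
  E <- psd$intensities
  check_design_covers(design, colnames(E))
  grp <- design$group_of[colnames(E)]
  ctrl <- design$control_group
  counts <- table(factor(grp, levels = names(design$dose_of)))
  treated <- setdiff(names(design$dose_of), ctrl)
  treated <- treated[counts[treated] >= 2]
  if (sum(grp == ctrl) < 2)
    stop("cv_treat requires a control group with at least 2 arrays")
  resid <- E
  for (l in unique(grp))
    resid[, grp == l] <- E[, grp == l, drop = FALSE] -
      rowMeans(E[, grp == l, drop = FALSE])
  ctrl_mean <- rowMeans(E[, grp == ctrl, drop = FALSE])
  ctrl_ss <- rowSums(resid[, grp == ctrl, drop = FALSE]^2)
  n_ctrl <- sum(grp == ctrl)
  values <- sapply(treated, function(l) {
    sel <- grp == l
    num <- sqrt(rowSums(resid[, sel, drop = FALSE]^2) + ctrl_ss) /
      (sum(sel) + n_ctrl)
    num / abs(rowMeans(E[, sel, drop = FALSE]) - ctrl_mean)
  })
  values <- matrix(values, nrow = nrow(E),
                   dimnames = list(rownames(E), treated))
  excluded <- !is.finite(values)
  if (!is.null(detection)) {
    absent_ctrl <- rowSums(!detection[rownames(E), grp == ctrl,
                                      drop = FALSE]) > 0
    for (l in treated)
      excluded[, l] <- excluded[, l] | absent_ctrl |
        rowSums(!detection[rownames(E), grp == l, drop = FALSE]) > 0
  }
  list(values = values, residuals = resid, excluded = excluded)
}

#' Spike-in coefficient of variation, rescaled to the CVbetween whiskers
#'
#' `CVspike_j` is the SD/mean of a spike-in probe set's normalized
#' intensities over all arrays (the arrays are technical replicates for
#' spike-ins). The whisker range `(lo, hi)` of the pooled CVbetween
#' distribution is the pair of extreme observed values lying inside the
#' Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear
#' interpolation, R type 7); `relativeCVspike_j = (CVspike_j - lo)/(hi -
#' lo)` maps the whisker range to `[0, 1]` and may legitimately fall
#' outside it.
#'
#' @param psd_spike [probe_set_data()] restricted to (or containing) the
#'   spike-in sets; if `probe_class` is available only spike-in rows are
#'   used.
#' @param cv_between_values numeric vector (or matrix) of pooled CVbetween
#'   values; `NA`s are dropped.
#' @return list with `cv_spike`, `relative_cv_spike` (named per set),
#'   `whisker_range` `(lo, hi)`, `q1`, `q3`.
#' @export
cv_spike_relative <- function(psd_spike, cv_between_values) {
  E <- psd_spike$intensities
  if (!is.null(psd_spike$probe_class))
    E <- E[psd_spike$probe_class == "spikein", , drop = FALSE]
  cv_spike <- apply(E, 1, stats::sd) / rowMeans(E)
  x <- as.numeric(cv_between_values)
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  inside <- x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr]
  lo <- min(inside); hi <- max(inside)
  if (hi <= lo)
    stop("degenerate CVbetween distribution: whisker range has zero width")
  list(cv_spike = cv_spike,
       relative_cv_spike = (cv_spike - lo) / (hi - lo),
       whisker_range = c(lo = lo, hi = hi), q1 = q[1], q3 = q[2])
}

#' Assemble the full CV quality-control report
#'
#' Convenience wrapper producing all four CV metrics from raw probe-level
#' data, normalized probe-set data and the experiment design.
#'
#' @param pld raw [probe_level_data()] (CVwithin is defined on raw data).
#' @param psd_norm normalized [probe_set_data()].
#' @param design an [experiment_design()] object.
#' @param detection optional present/absent matrix.
#' @return object of class `cv_report`: list with components `within`,
#'   `between`, `treat`, `spike` (each as returned by the individual
#'   functions).
#' @export
cv_report <- function(pld, psd_norm, design, detection = NULL) {
  w <- cv_within(pld, detection)
  b <- cv_between(psd_norm, design, detection)
  tr <- cv_treat(psd_norm, design, detection)
  pooled_b <- b$values[!b$excluded]
  sp <- cv_spike_relative(psd_norm, pooled_b)
  structure(list(within = w, between = b, treat = tr, spike = sp),
            class = "cv_report")
}

#' Write a CV report as TSV files plus a JSON summary
#' @param report a [cv_report()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(report$within$values, file.path(dir, "cv_within.tsv"),
                   id_column = "probe_set")
  write_matrix_tsv(report$between$values, file.path(dir, "cv_between.tsv"),
                   id_column = "probe_set")
  write_matrix_tsv(report$treat$values, file.path(dir, "cv_treat.tsv"),
                   id_column = "probe_set")
  utils::write.table(
    data.frame(probe_set = names(report$spike$cv_spike),
               cv_spike = report$spike$cv_spike,
               relative_cv_spike = report$spike$relative_cv_spike),
    file.path(dir, "cv_spike.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  summary_of <- function(x, excluded) {
    v <- x[!excluded]
    v <- v[is.finite(v)]
    list(median = stats::median(v),
         q1 = unname(stats::quantile(v, 0.25, type = 7)),
         q3 = unname(stats::quantile(v, 0.75, type = 7)), n = length(v))
  }
  js <- list(
    cv_within = summary_of(report$within$values, report$within$excluded),
    cv_between = summary_of(report$between$values, report$between$excluded),
    cv_treat = summary_of(report$treat$values, report$treat$excluded),
    relative_cv_spike = list(
      median = stats::median(report$spike$relative_cv_spike),
      whisker_lo = unname(report$spike$whisker_range["lo"]),
      whisker_hi = unname(report$spike$whisker_range["hi"])))
  jsonlite::write_json(js, file.path(dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
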