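#' Exiqon-style detection calls
#'
#' A probe passes on an array when (i) it is not flagged bad quality and
#' (ii) its linear-scale intensity exceeds `threshold_factor` times the
#' median of all linear probe intensities on that array. A probe set is
#' "present" when at least `min_probes` of its probes pass. The threshold
#' is applied on the linear scale (`2^E`): a multiple of a log2 value would
#' be scale-dependent.
#'
#' @param pld a [probe_level_data()] object (log2 intensities).
#' @param threshold_factor multiple of the array median.
#' @param min_probes minimum passing probes for a "present" call.
#' @return logical matrix (probe set x array), `TRUE` = present.
#' @export
detection_call_exiqon <- function(pld, threshold_factor = 1.5,
                                  min_probes = 2) {
  lin <- 2^pld$intensities
  thr <- threshold_factor * apply(lin, 2, stats::median)
  pass <- sweep(lin, 2, thr, ">") & !pld$flags
  ann <- aligned_annotation(pld)
  sets <- unique(ann$probe_set)
  idx <- split(seq_len(nrow(lin)), ann$probe_set)[sets]
  det <- t(vapply(idx, function(i)
    colSums(pass[i, , drop = FALSE]) >= min_probes,
    logical(ncol(lin))))
  colnames(det) <- colnames(lin)
  det
}

#' Wilcoxon rank-sum detection calls
#'
#' Affymetrix-style rule: for each probe set and array, the set's probe
#' intensities are compared against a matched background probe group with a
#' one-sided rank-sum test (set > background); the call is "present" when
#' the p-value is below `alpha`.
#'
#' @param pld a [probe_level_data()] object.
#' @param background_groups named list mapping probe-set id to a character
#'   vector of background probe ids (present in `pld`).
#' @param alpha presence threshold on the p-value.
#' @return logical matrix (tested probe set x array), `TRUE` = present.
#' @export
detection_call_wilcoxon <- function(pld, background_groups, alpha = 0.06) {
  ann <- aligned_annotation(pld)
  sets <- names(background_groups)
  if (is.null(sets) || !length(sets))
    stop("background_groups must be a non-empty named list")
  E <- pld$intensities
  det <- matrix(NA, length(sets), ncol(E),
                dimnames = list(sets, colnames(E)))
  for (j in sets) {
    bg <- background_groups[[j]]
    if (!length(bg))
      stop("empty background group for probe set ", j)
    if (!all(bg %in% rownames(E)))
      stop("background probes absent from the data for probe set ", j)
    probes <- ann$probe[ann$probe_set == j]
    if (!length(probes)) stop("unknown probe set ", j)
    for (k in seq_len(ncol(E))) {
      p <- rank_sum_greater(E[probes, k], E[bg, k])
      det[j, k] <- p < alpha
    }
  }
  det
}

#' One-sided rank-sum test p-value, P(set > background)
#'
#' Exact whenever feasible: the tie-free case uses the exact Wilcoxon
#' distribution; with ties, the permutation distribution of the midrank sum
#' is enumerated exactly when `choose(m+n, m)` is small enough, otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x numeric values of the tested group.
#' @param y numeric values of the background group.
#' @param max_enum enumeration budget on `choose(m+n, m)`.
#' @return p-value for the one-sided alternative `x > y`.
#' @export
rank_sum_greater <- function(x, y, max_enum = 2e5) {
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties) {
    return(suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = TRUE)$p.value))
  }
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  if (choose(m + n, m) <= max_enum) {
    combos <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[combos], nrow = m))
    return(mean(w_all >= w_obs - 1e-9))
  }
  mu <- m * (n + m + 1) / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 *
    ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
  stats::pnorm(w_obs - 0.5, mean = mu, sd = sqrt(sigma2),
               lower.tail = FALSE)
}
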