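#' Dose-response differential expression with moderated t-statistics
#'
#' Per probe set, ordinary least squares of the normalized intensity on the
#' normalized dose vector `D_k` (doses scaled to unit maximum by default),
#' followed by empirical-Bayes moderation of the residual variances in the
#' Smyth style: the per-set variances `s2_j` with `d_j` residual degrees of
#' freedom are shrunk toward a prior `(d0, s0^2)` estimated by a method of
#' moments on the log residual variances, giving
#' `s2_post = (d0 s0^2 + d s2) / (d0 + d)`; the moderated t uses `s2_post`
#' and `d0 + d` degrees of freedom. Benjamini-Hochberg FDR values are
#' reported alongside the raw p-values.
#'
#' @param psd normalized [probe_set_data()].
#' @param design an [experiment_design()] object; all doses equal is an
#'   error.
#' @param dose_normalization `"max"` (dose / max dose) or `"ordinal"`
#'   (0, 1, 2, ... dose levels).
#' @param prior_df optional fixed prior degrees of freedom `d0` (bypasses
#'   estimation; `0` recovers the ordinary t exactly, `Inf` the fully
#'   pooled t).
#' @param prior_var optional fixed prior variance `s0^2` (with `prior_df`).
#' @return a data.frame (one row per probe set): `probe_set`, `intercept`,
#'   `slope`, `s2`, `df`, `s2_post`, `t`, `p.value`, `fdr`, `t_ordinary`,
#'   `p_ordinary`; hyperparameters `d0`, `s0_2` and the dose vector are
#'   attached as attributes.
#' @export
fit_dose_response <- function(psd, design,
                              dose_normalization = c("max", "ordinal"),
                              prior_df = NULL, prior_var = NULL) {
  dose_normalization <- match.arg(dose_normalization)
  E <- psd$intensities
  if (ncol(E) < 3)
    stop("dose-response fit needs at least 3 arrays")
  D <- dose_vector(design, colnames(E), dose_normalization)
  if (length(unique(D)) < 2) stop("all doses are equal; no model to fit")
  X <- cbind(intercept = 1, dose = D)
  XtXi <- solve(crossprod(X))
  beta <- E %*% X %*% XtXi           # rows: (intercept, slope) per set
  fitted <- beta %*% t(X)
  res <- E - fitted
  d <- ncol(E) - 2
  s2 <- rowSums(res^2) / d
  c_slope <- XtXi["dose", "dose"]
  se_ord <- sqrt(s2 * c_slope)
  t_ord <- beta[, "dose"] / se_ord
  p_ord <- 2 * stats::pt(-abs(t_ord), df = d)
  if (is.null(prior_df)) {
    hyper <- estimate_variance_prior(s2, d)
  } else {
    hyper <- list(d0 = prior_df,
                  s0_2 = if (is.null(prior_var)) mean(s2) else prior_var)
  }
  s2_post <- squeeze_var(s2, d, hyper$d0, hyper$s0_2)
  t_mod <- beta[, "dose"] / sqrt(s2_post * c_slope)
  # total df capped at the pooled residual df of the whole dataset
  df_total <- min(hyper$d0 + d, nrow(E) * d)
  p_mod <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(probe_set = rownames(E),
                    intercept = beta[, "intercept"],
                    slope = beta[, "dose"],
                    s2 = s2, df = d, s2_post = s2_post,
                    t = t_mod, p.value = p_mod,
                    fdr = stats::p.adjust(p_mod, method = "BH"),
                    t_ordinary = t_ord, p_ordinary = p_ord,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- hyper$d0
  attr(out, "s0_2") <- hyper$s0_2
  attr(out, "dose") <- D
  out
}

#' Posterior (squeezed) variances
#'
#' `s2_post = (d0 s0^2 + d s2) / (d0 + d)`; `d0 = 0` returns `s2`
#' unchanged, `d0 = Inf` returns `s0^2` for every feature.
#'
#' @param s2 per-feature residual variances.
#' @param df residual degrees of freedom (scalar or vector).
#' @param d0 prior degrees of freedom.
#' @param s0_2 prior variance.
#' @return vector of posterior variances.
#' @export
squeeze_var <- function(s2, df, d0, s0_2) {
  if (is.infinite(d0)) return(rep(s0_2, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0_2 + df * s2) / (d0 + df)
}

#' Method-of-moments estimate of the variance prior (d0, s0^2)
#'
#' Under the hierarchical model `s2 ~ s0^2 F(d, d0)`,
#' `e = log s2 - digamma(d/2) + log(d/2)` has mean
#' `log s0^2 - digamma(d0/2) + log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond the sampling term `trigamma(d/2)`. Matching the
#' empirical mean and variance of `e` yields `d0` via an inverse-trigamma
#' Newton solve; a non-positive excess variance gives `d0 = Inf` (all
#' features share one variance).
#'
#' @param s2 residual variances (zeros are dropped from the fit).
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0` and `s0_2`.
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 >= 0
  if (sum(ok) < 2)
    stop("too few residual variances to estimate the prior")
  x <- s2[ok]
  m <- stats::median(x)
  if (m == 0) stop("more than half of the residual variances are zero; ",
                   "variance moderation is not meaningful")
  x <- pmax(x, 1e-5 * m)       # offset exact zeros away from log(0)
  z <- log(x)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion: one common variance; its arithmetic-mean
    # estimate is unbiased under the scaled-chi-square model
    d0 <- Inf
    s0_2 <- mean(x)
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(x) = y (y > 0), decreasing function of x
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Pairwise log2 differential expression with confidence intervals
#'
#' Difference of group means per probe set between two treatment groups,
#' with a 95% CI half-width computed as
#' `t_{0.975, df} x (difference / t)` where `t` is the pooled two-sample
#' t-statistic and `df = N_a + N_b - 2` (algebraically `t_{0.975, df} x
#' SE`; the quotient form is kept because it also defines the CI when only
#' a difference and its t-statistic are reported). A zero pooled variance
#' yields a CI half-width of 0.
#'
#' @param psd normalized [probe_set_data()].
#' @param design an [experiment_design()] object.
#' @param group_a treated group label (first term of the difference).
#' @param group_b reference group label.
#' @return data.frame: `probe_set`, `log2fc` (mean_a - mean_b), `t`, `df`,
#'   `ci_half_width`.
#' @export
pairwise_log2fc <- function(psd, design, group_a, group_b) {
  E <- psd$intensities
  check_design_covers(design, colnames(E))
  grp <- design$group_of[colnames(E)]
  for (g in c(group_a, group_b))
    if (sum(grp == g) < 2)
      stop("group '", g, "' must be present with at least 2 arrays")
  A <- E[, grp == group_a, drop = FALSE]
  B <- E[, grp == group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  diff <- rowMeans(A) - rowMeans(B)
  df <- na + nb - 2
  sp2 <- (rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- diff / se
  ci <- stats::qt(0.975, df) * se
  ci[se == 0] <- 0
  data.frame(probe_set = rownames(E), log2fc = diff, t = t, df = df,
             ci_half_width = ci, row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation with a leave-one-out confidence interval
#'
#' Spearman's rank correlation over all `n` pairs, with an interval given
#' by the 2.5th and 97.5th percentiles of the `n` correlations obtained by
#' omitting one pair at a time.
#'
#' @param x,y paired numeric vectors, `n >= 4`; constant vectors are an
#'   error (the rank correlation is undefined).
#' @return list with `r`, `ci_low`, `ci_high`, `loo` (the n leave-one-out
#'   correlations).
#' @export
spearman_loo_ci <- function(x, y) {
  n <- length(x)
  if (n < 4 || length(y) != n)
    stop("spearman_loo_ci needs paired vectors with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  r <- stats::cor(x, y, method = "spearman")
  loo <- vapply(seq_len(n), function(i)
    stats::cor(x[-i], y[-i], method = "spearman"), 0)
  ci <- stats::quantile(loo, c(0.025, 0.975), names = FALSE, type = 7)
  list(r = r, ci_low = ci[1], ci_high = ci[2], loo = loo)
}
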