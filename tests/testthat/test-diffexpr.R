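# diff_expr: dose-response model, moderated t, pairwise FC, qPCR, Spearman

make_dose_psd <- function(E, arrays = colnames(E)) make_psd(E)

std_design16 <- function() make_design(paste0("a", 1:16))

test_that("noiseless linear response is recovered exactly", {
  d <- std_design16()
  D <- unname(spikenorm:::dose_vector(d, paste0("a", 1:16)))
  E <- rbind(s1 = 1 + 0.5 * D, s2 = 7 - 2 * D)
  colnames(E) <- paste0("a", 1:16)
  fit <- fit_dose_response(make_psd(E), d)
  expect_equal(fit$slope, c(0.5, -2), tolerance = 1e-12)
  expect_equal(fit$intercept, c(1, 7), tolerance = 1e-12)
  expect_equal(fit$s2, c(0, 0), tolerance = 1e-20)
})

test_that("moderated t reduces to ordinary t at d0 = 0 and pooled at Inf", {
  set.seed(111)
  d <- std_design16()
  E <- matrix(rnorm(50 * 16, 8, 0.3), 50, 16,
              dimnames = list(paste0("s", 1:50), paste0("a", 1:16)))
  f0 <- fit_dose_response(make_psd(E), d, prior_df = 0)
  expect_equal(f0$t, f0$t_ordinary, tolerance = 1e-8)
  fInf <- fit_dose_response(make_psd(E), d, prior_df = Inf,
                            prior_var = 0.09)
  expect_equal(fInf$s2_post, rep(0.09, 50))
  # squeeze_var algebra
  expect_equal(squeeze_var(c(1, 2), 4, 2, 0.5), (2 * 0.5 + 4 * c(1, 2)) / 6)
})

test_that("moderated fit agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(112)
  d <- std_design16()
  D <- unname(spikenorm:::dose_vector(d, paste0("a", 1:16)))
  E <- matrix(rnorm(200 * 16, 8, 0.3), 200, 16,
              dimnames = list(paste0("s", 1:200), paste0("a", 1:16)))
  E[1:20, ] <- E[1:20, ] + outer(runif(20, -1, 1), D)
  fit <- fit_dose_response(make_psd(E), d)
  lf <- limma::eBayes(limma::lmFit(E, cbind(1, dose = D)))
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s0_2"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$t, unname(lf$t[, "dose"]), tolerance = 1e-8)
  expect_equal(fit$p.value, unname(lf$p.value[, "dose"]), tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  E <- matrix(rnorm(32), 2, 16,
              dimnames = list(c("s1", "s2"), paste0("a", 1:16)))
  d0 <- experiment_design(paste0("a", 1:16), rep("sham", 16), c(sham = 0))
  expect_error(fit_dose_response(make_psd(E), d0), "dose")
})

test_that("pairwise_log2fc matches the two-sample t oracle", {
  set.seed(113)
  d <- experiment_design(paste0("a", 1:8), rep(c("sham", "high"), each = 4),
                         c(sham = 0, high = 300))
  E <- matrix(rnorm(5 * 8, 8), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("a", 1:8)))
  pw <- pairwise_log2fc(make_psd(E), d, "high", "sham")
  for (j in 1:5) {
    tt <- t.test(E[j, 5:8], E[j, 1:4], var.equal = TRUE)
    expect_equal(pw$log2fc[j], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
    expect_equal(pw$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(pw$ci_half_width[j],
                 unname(diff(tt$conf.int)) / 2, tolerance = 1e-12)
  }
  # identical groups -> 0; zero-variance groups -> CI half-width 0
  Ec <- matrix(c(5, 5, 5, 5, 4, 4, 4, 4), 1, 8,
               dimnames = list("s", paste0("a", 1:8)))
  d2 <- experiment_design(paste0("a", 1:8), rep(c("high", "sham"), each = 4),
                          c(sham = 0, high = 300))
  pwc <- pairwise_log2fc(make_psd(Ec), d2, "high", "sham")
  expect_equal(pwc$log2fc, 1)
  expect_equal(pwc$ci_half_width, 0)
  expect_error(pairwise_log2fc(make_psd(Ec), d2, "missing", "sham"),
               "missing")
})

test_that("comparative_ct: sign conventions and control cancellation", {
  mk_qpcr <- function(shift_treated = 0, shift_all = 0) {
    samples <- paste0("m", 1:8)
    groups <- stats::setNames(rep(c("sham", "high"), each = 4), samples)
    rows <- list()
    for (s in samples) {
      extra <- if (groups[[s]] == "high") shift_treated else 0
      for (r in 1:3) {
        rows[[length(rows) + 1]] <-
          data.frame(mirna = "miR-x", sample = s, replicate = r,
                     ct = 20 + extra + shift_all + 0.1 * r)
        rows[[length(rows) + 1]] <-
          data.frame(mirna = "sno135", sample = s, replicate = r,
                     ct = 15 + shift_all + 0.05 * r)
      }
    }
    list(tab = do.call(rbind, rows), groups = groups)
  }
  base <- mk_qpcr()
  res0 <- comparative_ct(base$tab, base$groups, c("high", "sham"))
  expect_equal(res0$minus_ddct, 0)
  # treated Ct 2 cycles higher (less miRNA) -> -2 under down_negative
  up <- mk_qpcr(shift_treated = 2)
  res2 <- comparative_ct(up$tab, up$groups, c("high", "sham"))
  expect_equal(res2$minus_ddct, -2)
  expect_lt(res2$p.value, 0.05)
  # 2^(-2): four-fold decrease, consistent with the fold-change reading
  expect_equal(2^res2$minus_ddct, 0.25)
  # literal printed convention mirrors the sign
  resp <- comparative_ct(up$tab, up$groups, c("high", "sham"),
                         sign_convention = "as_printed")
  expect_equal(resp$minus_ddct, 2)
  # a global shift of all Ct values (target and control alike) cancels
  shifted <- mk_qpcr(shift_treated = 2, shift_all = 1)
  expect_equal(comparative_ct(shifted$tab, shifted$groups,
                              c("high", "sham"))$minus_ddct, -2)
  # missing endogenous control errors with the sample name
  broken <- base$tab[!(base$tab$mirna == "sno135" & base$tab$sample == "m3"), ]
  expect_error(comparative_ct(broken, base$groups, c("high", "sham")), "m3")
})

test_that("spearman_loo_ci matches brute-force leave-one-out enumeration", {
  expect_equal(spearman_loo_ci(1:10, log(1:10 + 2))[c("r", "ci_low",
                                                      "ci_high")],
               list(r = 1, ci_low = 1, ci_high = 1))
  expect_equal(spearman_loo_ci(1:10, 10:1)$r, -1)
  expect_error(spearman_loo_ci(1:10, rep(1, 10)), "constant")
  expect_error(spearman_loo_ci(1:3, 3:1), "n >= 4")
  set.seed(114)
  x <- rnorm(24); y <- 0.8 * x + rnorm(24, sd = 0.5)
  got <- spearman_loo_ci(x, y)
  loo <- vapply(1:24, function(i)
    cor(rank(x[-i]), rank(y[-i])), 0)   # Pearson on ranks = Spearman
  expect_equal(got$loo, loo, tolerance = 1e-12)
  expect_equal(got$ci_low, quantile(loo, 0.025, names = FALSE),
               tolerance = 1e-12)
  expect_equal(got$ci_high, quantile(loo, 0.975, names = FALSE),
               tolerance = 1e-12)
})
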