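# scn_core: assumption checks, first step, correction function, application

test_that("extract_spikein pulls spike sets and requires at least 2", {
  set.seed(21)
  sim <- simulate_experiment(simulation_config(
    n_mirna_sets = 30, probes_per_spike_set = 4, seed = 21))
  psd <- summarize_probesets(sim$data)
  sm <- extract_spikein(psd, sim$data)
  expect_identical(nrow(sm$values), 10L)
  expect_identical(ncol(sm$values), 16L)
  expect_equal(sm$row_means, rowMeans(sm$values))
  # constant rows have their constant as row mean
  E <- matrix(5, 2, 3, dimnames = list(c("sA", "sB"), paste0("a", 1:3)))
  expect_equal(unname(make_spikein(E)$row_means), c(5, 5))
  # fewer than 2 spike sets is a configuration error
  one <- make_pld(matrix(1:4 / 2, 2, 2,
                         dimnames = list(c("p1", "p2"), c("a", "b"))),
                  c("s1", "s1"), "spikein")
  expect_error(extract_spikein(summarize_probesets(one), one),
               "at least 2 spike-in")
})

test_that("A1 passes for affinely related rows and fails for anti-correlated", {
  base <- c(0, 1, 2, 3)
  E <- rbind(sA = 4 + base, sB = 8 + 2 * base, sC = 12 + 0.5 * base)
  colnames(E) <- paste0("a", 1:4)
  a1 <- check_assumption_a1(make_spikein(E))
  expect_true(a1$pass)
  expect_equal(a1$median_offdiag, 1)
  anti <- rbind(sA = c(1, 2, 3), sB = c(3, 2, 1))
  colnames(anti) <- paste0("a", 1:3)
  expect_false(check_assumption_a1(make_spikein(anti))$pass)
  expect_equal(check_assumption_a1(make_spikein(anti))$median_offdiag, -1)
})

test_that("A1 at SNR 10 passes and matches the direct correlation oracle", {
  set.seed(31)
  K <- 16
  shared <- rnorm(K, sd = 1)
  E <- t(vapply(1:8, function(j) 6 + j + shared + rnorm(K, sd = 0.1),
                numeric(K)))
  dimnames(E) <- list(paste0("s", 1:8), paste0("a", 1:K))
  a1 <- check_assumption_a1(make_spikein(E))
  expect_true(a1$pass)
  expect_gte(a1$median_offdiag, 0.9)
  C <- cor(t(E))
  expect_equal(a1$median_offdiag, median(C[lower.tri(C)]))
  expect_equal(a1$mean_offdiag, mean(C[lower.tri(C)]))
})

test_that("A1 handles constant rows with a warning record", {
  E <- rbind(sA = c(1, 2, 3, 4), sB = c(5, 5, 5, 5), sC = c(2, 4, 6, 8))
  colnames(E) <- paste0("a", 1:4)
  a1 <- check_assumption_a1(make_spikein(E))
  expect_match(a1$warnings, "sB")
  expect_equal(a1$corr["sB", "sA"], 0)
})

test_that("A2 compares pooled within-set SD against the minimum mean gap", {
  mk <- function(means, sd_probe, n_probes = 4, K = 4) {
    sets <- paste0("s", seq_along(means))
    # probe offsets constructed to have sample SD exactly sd_probe
    off <- scale(seq_len(n_probes), scale = FALSE)
    off <- off / sd(off) * sd_probe
    pl <- do.call(rbind, lapply(means, function(m)
      matrix(m + off, n_probes, K)))
    rownames(pl) <- paste0(rep(sets, each = n_probes), "_p",
                           seq_len(n_probes))
    colnames(pl) <- paste0("a", 1:K)
    values <- t(vapply(seq_along(means), function(j)
      colMeans(pl[((j - 1) * n_probes + 1):(j * n_probes), ]), numeric(K)))
    rownames(values) <- sets
    make_spikein(values, pl,
                 stats::setNames(rep(sets, each = n_probes), rownames(pl)))
  }
  expect_true(check_assumption_a2(mk(c(4, 8, 12), 0.1))$pass)
  expect_false(check_assumption_a2(mk(c(4, 4, 12), 0.1))$pass)  # gap 0
  a2 <- check_assumption_a2(mk(c(4, 5, 6), 1.2))
  expect_false(a2$pass)                                         # 1.2 > 1.0
  expect_equal(unname(a2$within_sd), rep(1.2, 3), tolerance = 1e-12)
  expect_equal(a2$min_gap, 1.0)
})

test_that("A3 coverage with bounded extrapolation, including the boundary", {
  mk_full <- function(lo, hi) {
    # miRNA values uniform over [lo, hi] so the 5th-95th band is known
    vals <- seq(lo, hi, length.out = 201)
    E <- matrix(vals, 201, 2, dimnames = list(paste0("m", 1:201),
                                              c("a1", "a2")))
    make_psd(E, probe_class = stats::setNames(rep("mirna", 201),
                                              rownames(E)))
  }
  sp <- function(lo, hi) {
    E <- rbind(sA = c(lo, lo), sB = c(hi, hi))
    colnames(E) <- c("a1", "a2")
    make_spikein(E)
  }
  full <- mk_full(5, 13)   # band approx [5.4, 12.6]
  expect_true(check_assumption_a3(sp(4, 14), full)$pass)
  expect_false(check_assumption_a3(sp(4, 8), full, max_extrapolation = 2)$pass)
  # boundary: band upper end exceeds the spike max by exactly 2.0
  vals <- seq(0, 10, length.out = 201)
  E <- matrix(vals, 201, 2, dimnames = list(paste0("m", 1:201),
                                            c("a1", "a2")))
  full2 <- make_psd(E, probe_class = stats::setNames(rep("mirna", 201),
                                                     rownames(E)))
  band <- quantile(E, c(0.05, 0.95), names = FALSE)   # (0.5, 9.5)
  exact <- sp(band[1], band[2] - 2)
  expect_true(check_assumption_a3(exact, full2, max_extrapolation = 2)$pass)
  shy <- sp(band[1], band[2] - 2 - 1e-6)
  expect_false(check_assumption_a3(shy, full2, max_extrapolation = 2)$pass)
})

test_that("first step reproduces the hand-worked two-set example exactly", {
  E <- rbind(s1 = c(1, 3), s2 = c(2, 6))
  colnames(E) <- c("a1", "a2")
  sc <- compute_spikein_corrections(make_spikein(E))
  expect_equal(unname(sc$row_norms), c(sqrt(2), 2 * sqrt(2)))
  expect_equal(unname(sc$U), rbind(c(-1, 1) / sqrt(2), c(-1, 1) / sqrt(2)))
  expect_equal(unname(sc$u_mean), c(-1, 1) / sqrt(2))
  expect_equal(unname(sc$delta_s), rbind(c(-1, 1), c(-2, 2)))
  expect_equal(max(abs(sc$residuals)), 0)
})

test_that("first step yields zero corrections for constant rows", {
  E <- matrix(c(4, 4, 4, 9, 9, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("a", 1:3)))
  sc <- compute_spikein_corrections(make_spikein(E))
  expect_equal(max(abs(sc$delta_s)), 0)
  expect_equal(max(abs(sc$residuals)), 0)
})

test_that("rank-1 plus noise: residuals strictly smaller than deviations", {
  set.seed(41)
  u <- scale(rnorm(12), scale = FALSE)[, 1]
  r <- runif(8, 0.5, 2)
  E <- 6 + outer(r, u) + matrix(rnorm(96, sd = 0.05), 8, 12)
  dimnames(E) <- list(paste0("s", 1:8), paste0("a", 1:12))
  sc <- compute_spikein_corrections(make_spikein(E))
  dev <- E - rowMeans(E)
  expect_lt(sqrt(sum(sc$residuals^2)), sqrt(sum(dev^2)))
  # and the extracted corrections match a direct recomputation
  U2 <- dev / sqrt(rowSums(dev^2))
  expect_equal(sc$delta_s,
               outer(sqrt(rowSums(dev^2)), colMeans(U2)),
               ignore_attr = TRUE)
})

test_that("correction function: constant corrections stay constant", {
  E <- rbind(s1 = c(4, 4), s2 = c(8, 8), s3 = c(12, 12))
  colnames(E) <- c("a1", "a2")
  sm <- make_spikein(E + cbind(rep(0.3, 3), rep(-0.3, 3)))
  sc <- compute_spikein_corrections(sm)
  full <- matrix(seq(2, 14, length.out = 20), 10, 2,
                 dimnames = list(paste0("p", 1:10), c("a1", "a2")))
  cf <- build_correction_function(sc, sm, full)
  xs <- seq(2, 14, by = 0.5)
  expect_equal(predict(cf, xs, "a1"), rep(0.3, length(xs)), tolerance = 1e-12)
  expect_equal(predict(cf, xs, "a2"), rep(-0.3, length(xs)), tolerance = 1e-12)
})

test_that("stabilization and extrapolation knots follow the stated rules", {
  # spike sets at x = 4, 6, 8, 10, 12 with known per-array deltas.
  # Equal-sign deviations mirrored across the two arrays are recovered
  # exactly by the rank-1 first step: all U rows coincide.
  x <- c(4, 6, 8, 10, 12)
  delta_a1 <- c(0.1, 0.15, 0.3, 0.2, 0.4)
  E <- cbind(a1 = x + delta_a1, a2 = x - delta_a1)
  rownames(E) <- paste0("s", 1:5)
  sm <- make_spikein(E)
  sc <- compute_spikein_corrections(sm)
  expect_equal(unname(sc$delta_s[, "a1"]), delta_a1, tolerance = 1e-12)
  full <- rbind(p1 = c(2, 2), p2 = c(14, 14))
  colnames(full) <- c("a1", "a2")
  cf <- build_correction_function(sc, sm, full)
  kn <- cf$knots[["a1"]]
  # prepended knot at the dataset minimum with the closest spike's delta
  expect_equal(kn$x[1], 2)
  expect_equal(kn$raw_delta[1], 0.1)
  expect_identical(kn$provenance[1], "stabilize")
  # appended knots at integers 13, 14 on the line through (10,0.2),(12,0.4)
  expect_true(all(c(13, 14) %in% kn$x))
  expect_equal(kn$raw_delta[kn$x == 13], 0.5)
  expect_equal(kn$raw_delta[kn$x == 14], 0.6)
  expect_identical(kn$provenance[kn$x == 14], "extrapolate")
  expect_true(all(diff(kn$x) > 0))
  expect_equal(range(kn$x), c(2, 14))
})

test_that("apply_correction subtracts the interpolated correction entrywise", {
  set.seed(51)
  # arbitrary correction function from random spike deviations
  E_sp <- 6 + outer(runif(5, 0.5, 1.5), scale(rnorm(4), scale = FALSE)[, 1])
  E_sp <- E_sp + matrix(rnorm(20, sd = 0.05), 5, 4)
  dimnames(E_sp) <- list(paste0("s", 1:5), paste0("a", 1:4))
  sm <- make_spikein(E_sp)
  sc <- compute_spikein_corrections(sm)
  data <- matrix(runif(200, 2, 12), 50, 4,
                 dimnames = list(paste0("p", 1:50), paste0("a", 1:4)))
  cf <- build_correction_function(sc, sm, data)
  pld <- make_pld(data, rep(paste0("set", 1:10), each = 5), "mirna")
  out <- apply_correction(pld, cf)
  for (k in paste0("a", 1:4)) {
    kn <- cf$knots[[k]]
    expect_equal(out$intensities[, k],
                 data[, k] - interp_oracle(kn$x, kn$delta, data[, k]),
                 tolerance = 1e-12)
  }
  # zero correction is the identity; constant correction a per-array shift
  cf0 <- cf
  for (k in names(cf0$knots)) cf0$knots[[k]]$delta <- 0
  expect_equal(apply_correction(pld, cf0)$intensities, data)
  cfc <- cf
  for (k in names(cfc$knots)) cfc$knots[[k]]$delta <- 0.25
  expect_equal(apply_correction(pld, cfc)$intensities, data - 0.25)
  # unknown array label errors by name
  bad <- pld
  colnames(bad$intensities) <- c(paste0("a", 1:3), "zz")
  colnames(bad$flags) <- colnames(bad$intensities)
  expect_error(apply_correction(bad, cf), "zz")
})

test_that("scn_normalize falls back when spike-ins are absent", {
  set.seed(61)
  E <- matrix(rnorm(40, 8), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("a", 1:4)))
  pld <- make_pld(E, rep(paste0("s", 1:5), each = 2), "mirna")
  expect_warning(res <- scn_normalize(pld), "MEDIAN")
  expect_true(res$report$fallback_used)
  expect_identical(res$method_used, "median")
  expect_equal(res$probesets$intensities,
               median_normalize(summarize_probesets(pld))$intensities)
})

test_that("noiseless constant-bias data: SCN is exactly idempotent", {
  cfg <- simulation_config(bias_model = "constant", bias_amplitude = 0.3,
                           probe_noise_sd = 0, bio_noise_sd = 0,
                           fraction_de = 0, flag_rate = 0, seed = 71,
                           n_mirna_sets = 60, probes_per_spike_set = 8)
  sim <- simulate_experiment(cfg)
  r1 <- scn_normalize(sim$data, sim$design)
  expect_identical(r1$method_used, "scn")
  # a second application changes nothing (to fp noise): the corrected
  # spike rows are constant, so any further correction is zero
  r2 <- suppressWarnings(scn_normalize(r1$probelevel, sim$design))
  expect_equal(r2$probesets$intensities, r1$probesets$intensities,
               tolerance = 1e-8)
})

test_that("second pass correction is much smaller than the first (smooth bias)", {
  cfg <- simulation_config(probe_noise_sd = 0, bio_noise_sd = 0,
                           probe_effect_sd = 0, fraction_de = 0,
                           flag_rate = 0, seed = 72, n_mirna_sets = 60)
  sim <- simulate_experiment(cfg)
  r1 <- scn_normalize(sim$data, sim$design)
  first_mag <- max(abs(r1$probesets$intensities -
                         summarize_probesets(sim$data)$intensities))
  r2 <- suppressWarnings(scn_normalize(r1$probelevel, sim$design))
  second_mag <- max(abs(r2$probesets$intensities -
                          r1$probesets$intensities))
  expect_lt(second_mag, first_mag)
})
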