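#' Simulation configuration for a synthetic miRNA array experiment
#'
#' Defaults emulate the structure of the study design the method was built
#' for: 16 arrays in 4 dose groups of 4 biological replicates (doses 0, 75,
#' 150 and 300 units), 600 miRNA probe sets of 4 replicate probes, and 10
#' spike-in probe sets ("a" to "j") of 48 probes each spanning log2
#' intensities 4 to 14.
#'
#' Bias models (`bias_model`):
#' * `"smooth"`: `b_k(x) = a_k * s(x)` with a shared cubic smoothstep shape
#'   `s(x) = 0.3 + 0.7 * (3 t^2 - 2 t^3)`, `t` the position of `x` within
#'   the spike intensity range, and zero-sum per-array amplitudes `a_k`
#'   scaled so `max |a_k| = bias_amplitude`. The shape is sign-constant and
#'   separable from the array index, the bias class an intensity-dependent
#'   multi-array correction can represent; the 0.3 floor keeps the bias
#'   non-degenerate at the low-intensity end.
#' * `"constant"`: intensity-independent offsets `a_k`, the symmetric
#'   ladder `seq(-A, A, length = K)` (zero mean, and zero median for even
#'   K), the degenerate case in which SCN reduces to MEDIAN.
#' * `"none"`: no array bias.
#'
#' `spike_deviation_sd > 0` adds independent per-(spike set, array) noise,
#' i.e. incoherent spike deviations that violate assumption A1 by
#' construction (a controlled A0/A1 stress test).
#'
#' @param groups data.frame with columns `group`, `dose`.
#' @param n_replicates biological replicates per group.
#' @param n_mirna_sets,probes_per_set miRNA probe sets and probes per set.
#' @param n_spike_sets,probes_per_spike_set spike-in sets and probes each.
#' @param spike_level_range log2 range spanned by the spike concentrations
#'   (levels are evenly spaced over it).
#' @param mirna_baseline_range log2 range of miRNA baseline draws.
#' @param bias_model `"smooth"`, `"constant"` or `"none"`.
#' @param bias_amplitude maximum per-array bias magnitude, log2 units.
#' @param probe_noise_sd per-measurement noise SD, log2 units.
#' @param bio_noise_sd biological replicate noise SD (miRNA sets only).
#' @param probe_effect_sd SD of fixed per-probe affinity offsets.
#' @param spike_deviation_sd SD of incoherent per-(spike set, array) noise.
#' @param fraction_de fraction of miRNA sets with a true dose response.
#' @param slope_range magnitude range of the differential slopes (per unit
#'   normalized dose).
#' @param global_decrease if `TRUE`, 90% of differential slopes are
#'   negative and a further `global_decrease_fraction` of all miRNA sets
#'   receive a small negative slope drawn from `global_decrease_range`,
#'   emulating a dataset-wide decrease in miRNA expression.
#' @param global_decrease_fraction,global_decrease_range see above.
#' @param flag_rate Bernoulli rate of bad-quality flags.
#' @param seed master RNG seed; all draws derive from it deterministically.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(
    groups = data.frame(group = c("sham", "low", "medium", "high"),
                        dose = c(0, 75, 150, 300)),
    n_replicates = 4,
    n_mirna_sets = 600, probes_per_set = 4,
    n_spike_sets = 10, probes_per_spike_set = 48,
    spike_level_range = c(4, 14),
    mirna_baseline_range = c(5, 13),
    bias_model = c("smooth", "constant", "none"),
    bias_amplitude = 0.5,
    probe_noise_sd = 0.05, bio_noise_sd = 0.1, probe_effect_sd = 0.1,
    spike_deviation_sd = 0,
    fraction_de = 0.1, slope_range = c(0.5, 2),
    global_decrease = FALSE, global_decrease_fraction = 0.6,
    global_decrease_range = c(0.1, 0.5),
    flag_rate = 0.01, seed = 1) {
  cfg <- list(groups = groups, n_replicates = n_replicates,
              n_mirna_sets = n_mirna_sets, probes_per_set = probes_per_set,
              n_spike_sets = n_spike_sets,
              probes_per_spike_set = probes_per_spike_set,
              spike_level_range = spike_level_range,
              mirna_baseline_range = mirna_baseline_range,
              bias_model = match.arg(bias_model),
              bias_amplitude = bias_amplitude,
              probe_noise_sd = probe_noise_sd, bio_noise_sd = bio_noise_sd,
              probe_effect_sd = probe_effect_sd,
              spike_deviation_sd = spike_deviation_sd,
              fraction_de = fraction_de, slope_range = slope_range,
              global_decrease = global_decrease,
              global_decrease_fraction = global_decrease_fraction,
              global_decrease_range = global_decrease_range,
              flag_rate = flag_rate, seed = seed)
  stopifnot(cfg$n_mirna_sets >= 1, cfg$probes_per_set >= 1,
            cfg$n_spike_sets >= 1, cfg$probes_per_spike_set >= 1,
            cfg$probe_noise_sd >= 0, cfg$bio_noise_sd >= 0,
            cfg$bias_amplitude >= 0, cfg$flag_rate >= 0, cfg$flag_rate <= 1,
            diff(cfg$spike_level_range) > 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

# shared cubic bias shape over the spike intensity range
bias_shape <- function(x, range, base = 0.3) {
  t <- pmin(pmax((x - range[1]) / (range[2] - range[1]), 0), 1)
  base + (1 - base) * (3 * t^2 - 2 * t^3)
}

#' Evaluate a simulated per-array bias function from its stored truth
#' @param truth the `truth` element returned by [simulate_experiment()].
#' @param x numeric vector of log2 intensities.
#' @param array array label.
#' @return numeric vector `b_k(x)`.
#' @export
true_bias <- function(truth, x, array) {
  a <- truth$bias$amplitudes[[array]]
  switch(truth$bias$model,
         none = rep(0, length(x)),
         constant = rep(a, length(x)),
         smooth = a * bias_shape(x, truth$bias$shape_range,
                                 truth$bias$shape_base))
}

#' Simulate a complete synthetic miRNA array experiment
#'
#' Generates probe-level log2 intensities
#' `E_ik = mu_ik + b_k(mu_ik) + biological noise + probe noise`, where
#' `mu_ik` is the noise-free expected intensity (baseline + dose response +
#' probe affinity for miRNA probes; spiked level + probe affinity for
#' spike-in probes) and `b_k` is the injected array bias, applied to every
#' probe as a function of its expected (not realized) intensity so the
#' ground truth stays well defined. Spike-in probes carry no biological or
#' treatment term. Deterministic under the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with `data` ([probe_level_data()]), `design`
#'   ([experiment_design()]) and `truth` (bias closed form and sampled
#'   grid, true slopes and baselines, spike levels, differential set ids,
#'   seed).
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  groups <- rep(cfg$groups$group, each = cfg$n_replicates)
  arrays <- paste(groups, rep(seq_len(cfg$n_replicates),
                              times = nrow(cfg$groups)), sep = "_")
  K <- length(arrays)
  doses <- stats::setNames(cfg$groups$dose, cfg$groups$group)
  design <- experiment_design(arrays, groups, doses)
  D <- dose_vector(design, arrays)

  mirna_sets <- sprintf("mir_%04d", seq_len(cfg$n_mirna_sets))
  spike_sets <- paste0("spike_", letters[seq_len(cfg$n_spike_sets)])
  spike_levels <- stats::setNames(
    seq(cfg$spike_level_range[1], cfg$spike_level_range[2],
        length.out = cfg$n_spike_sets), spike_sets)

  # draw order fixed: baselines, DE structure, probe effects, bias,
  # then noise matrices; regenerating with the same seed is bit-identical
  baselines <- stats::setNames(
    stats::runif(cfg$n_mirna_sets, cfg$mirna_baseline_range[1],
                 cfg$mirna_baseline_range[2]), mirna_sets)
  slopes <- stats::setNames(numeric(cfg$n_mirna_sets), mirna_sets)
  n_de <- round(cfg$fraction_de * cfg$n_mirna_sets)
  de_sets <- if (n_de > 0) sample(mirna_sets, n_de) else character(0)
  if (n_de > 0) {
    signs <- if (cfg$global_decrease)
      sample(c(-1, 1), n_de, replace = TRUE, prob = c(0.9, 0.1))
    else sample(c(-1, 1), n_de, replace = TRUE)
    slopes[de_sets] <- signs *
      stats::runif(n_de, cfg$slope_range[1], cfg$slope_range[2])
  }
  if (cfg$global_decrease) {
    n_gd <- round(cfg$global_decrease_fraction * cfg$n_mirna_sets)
    gd_sets <- sample(mirna_sets, n_gd)
    slopes[gd_sets] <- slopes[gd_sets] -
      stats::runif(n_gd, cfg$global_decrease_range[1],
                   cfg$global_decrease_range[2])
  }

  mirna_probes <- paste0(rep(mirna_sets, each = cfg$probes_per_set), "_p",
                         rep(seq_len(cfg$probes_per_set), cfg$n_mirna_sets))
  spike_probes <- paste0(rep(spike_sets, each = cfg$probes_per_spike_set),
                         "_p", sprintf("%02d", rep(
                           seq_len(cfg$probes_per_spike_set),
                           cfg$n_spike_sets)))
  probes <- c(mirna_probes, spike_probes)
  n_probes <- length(probes)
  probe_set_of <- c(rep(mirna_sets, each = cfg$probes_per_set),
                    rep(spike_sets, each = cfg$probes_per_spike_set))
  probe_effects <- stats::rnorm(n_probes, 0, cfg$probe_effect_sd)

  a_k <- switch(cfg$bias_model,
    none = stats::setNames(numeric(K), arrays),
    constant = stats::setNames(
      seq(-cfg$bias_amplitude, cfg$bias_amplitude, length.out = K), arrays),
    smooth = {
      a <- stats::rnorm(K)
      a <- a - mean(a)
      if (max(abs(a)) > 0) a <- a * cfg$bias_amplitude / max(abs(a))
      stats::setNames(a, arrays)
    })

  # noise-free expected intensity mu_ik
  is_mirna_probe <- probe_set_of %in% mirna_sets
  base_i <- ifelse(is_mirna_probe,
                   baselines[probe_set_of], spike_levels[probe_set_of]) +
    probe_effects
  slope_i <- ifelse(is_mirna_probe, slopes[probe_set_of], 0)
  mu <- outer(base_i, rep(1, K)) + outer(slope_i, D)
  dimnames(mu) <- list(probes, arrays)

  bias <- mu
  for (k in arrays)
    bias[, k] <- switch(cfg$bias_model,
                        none = 0,
                        constant = a_k[[k]],
                        smooth = a_k[[k]] *
                          bias_shape(mu[, k], cfg$spike_level_range))

  bio <- matrix(0, n_probes, K)
  if (cfg$bio_noise_sd > 0) {
    per_set <- matrix(stats::rnorm(cfg$n_mirna_sets * K, 0,
                                   cfg$bio_noise_sd),
                      cfg$n_mirna_sets, K, dimnames = list(mirna_sets, NULL))
    bio[is_mirna_probe, ] <- per_set[probe_set_of[is_mirna_probe], ]
  }
  spike_dev <- matrix(0, n_probes, K)
  if (cfg$spike_deviation_sd > 0) {
    per_spike <- matrix(stats::rnorm(cfg$n_spike_sets * K, 0,
                                     cfg$spike_deviation_sd),
                        cfg$n_spike_sets, K,
                        dimnames = list(spike_sets, NULL))
    spike_dev[!is_mirna_probe, ] <- per_spike[probe_set_of[!is_mirna_probe], ]
  }
  noise <- matrix(stats::rnorm(n_probes * K, 0, cfg$probe_noise_sd),
                  n_probes, K)
  E <- mu + bias + bio + spike_dev + noise
  flags <- matrix(stats::runif(n_probes * K) < cfg$flag_rate, n_probes, K,
                  dimnames = dimnames(E))

  annotation <- data.frame(
    probe = probes, probe_set = probe_set_of,
    probe_class = ifelse(is_mirna_probe, "mirna", "spikein"),
    stringsAsFactors = FALSE)
  pld <- probe_level_data(E, annotation, flags = flags, channel = "Hy3")

  grid <- seq(floor(min(E)), ceiling(max(E)), by = 0.1)
  truth <- list(
    bias = list(model = cfg$bias_model,
                amplitudes = as.list(a_k),
                shape_range = cfg$spike_level_range,
                shape_base = 0.3,
                grid_x = grid,
                grid_values = stats::setNames(lapply(arrays, function(k)
                  switch(cfg$bias_model,
                         none = rep(0, length(grid)),
                         constant = rep(a_k[[k]], length(grid)),
                         smooth = a_k[[k]] *
                           bias_shape(grid, cfg$spike_level_range))),
                  arrays)),
    slopes = slopes, baselines = baselines, de_sets = de_sets,
    spike_levels = spike_levels, dose = D, seed = cfg$seed)
  list(data = pld, design = design, truth = truth)
}

#' Write a simulated experiment as a text fixture directory
#'
#' Produces ImaGene-dialect files (one per array), the probe annotation
#' TSV, the design TSV, and a `truth.json` carrying the injected bias in
#' closed form plus a sampled grid, sufficient to recompute the expected
#' correction on any intensity grid.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory.
#' @return invisibly, a list of the written paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imagene <- write_imagene(sim$data, dir)
  ann_path <- file.path(dir, "annotation.tsv")
  utils::write.table(sim$data$annotation, ann_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  design_path <- file.path(dir, "design.tsv")
  write_design_tsv(sim$design, design_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(imagene = imagene, annotation = ann_path,
                 design = design_path, truth = truth_path))
}

#' Read back a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @param background background policy passed to [read_imagene()].
#' @return list with `data`, `design`, `truth`.
#' @export
read_fixture <- function(dir, background = "none") {
  design <- read_design_tsv(file.path(dir, "design.tsv"))
  paths <- stats::setNames(
    file.path(dir, paste0(names(design$group_of), ".txt")),
    names(design$group_of))
  pld <- read_imagene(paths, file.path(dir, "annotation.tsv"),
                      background = background)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(data = pld, design = design, truth = truth)
}
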