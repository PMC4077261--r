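#' Default pipeline configuration
#'
#' Defaults encode the method's printed constants: A1 threshold 0.5, LOWESS
#' span 0.4, Exiqon detection threshold factor 1.5, Wilcoxon alpha 0.06.
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `input` (fixture directory with ImaGene files +
#'   `annotation.tsv` + `design.tsv`, or `NULL` to simulate), `simulate`
#'   (list of [simulation_config()] overrides), `method` (`"scn"`,
#'   `"median"`, `"quantile"`), `level` (`"probeset"` or `"probe"`, for the
#'   baseline methods), `a1_threshold`, `max_extrapolation`,
#'   `lowess_frac`, `detection` (`"exiqon"`, `"none"`), `de` (list:
#'   `enabled`, `pairwise` = `c(group_a, group_b)` or `NULL`),
#'   `background` (ImaGene import policy), `out_dir`, `seed`.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(input = NULL, simulate = list(), method = "scn",
              level = "probeset", a1_threshold = 0.5,
              max_extrapolation = 2, lowess_frac = 0.4,
              detection = "exiqon", background = "none",
              de = list(enabled = TRUE, pairwise = NULL),
              out_dir = "spikenorm_out", seed = 1)
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("de", "simulate") && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  if (!cfg$method %in% c("scn", "median", "quantile"))
    stop("unknown normalization method: ", cfg$method)
  if (!cfg$detection %in% c("exiqon", "none"))
    stop("unknown detection rule: ", cfg$detection)
  if (cfg$a1_threshold < -1 || cfg$a1_threshold > 1)
    stop("a1_threshold must lie in [-1, 1]")
  if (cfg$lowess_frac <= 0 || cfg$lowess_frac > 1)
    stop("lowess_frac must lie in (0, 1]")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration file (JSON, or YAML when available)
#' @param path configuration file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline: input/simulate, normalize, QC, DE
#'
#' Stages: (1) load a fixture directory or simulate an experiment; (2)
#' median-summarize and normalize with the selected method (SCN applies
#' its assumption checks and may fall back to MEDIAN); (3) detection calls
#' and CV metrics; (4) dose-response differential expression and an
#' optional pairwise comparison. All outputs are plain TSV/JSON in
#' `out_dir`; the run is deterministic given the config and seed, and no
#' timestamps are written so identical runs produce byte-identical
#' bundles.
#'
#' @param cfg a [pipeline_config()] (or a list accepted by it).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- do.call(pipeline_config, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$input)) {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulate, list(seed = cfg$seed)))
    sim <- simulate_experiment(sim_cfg)
    pld <- sim$data; design <- sim$design
  } else {
    fx <- read_fixture(cfg$input, background = cfg$background)
    pld <- fx$data; design <- fx$design
  }
  psd_raw <- summarize_probesets(pld)
  report <- NULL
  correction <- NULL
  if (cfg$method == "scn") {
    res <- scn_normalize(pld, design, a1_threshold = cfg$a1_threshold,
                         max_extrapolation = cfg$max_extrapolation,
                         lowess_frac = cfg$lowess_frac)
    psd_norm <- res$probesets
    report <- res$report
    correction <- res$correction
    method_used <- res$method_used
  } else {
    normalizer <- if (cfg$method == "median") median_normalize
                  else quantile_normalize
    psd_norm <- if (cfg$level == "probe")
      summarize_probesets(normalizer(pld)) else normalizer(psd_raw)
    method_used <- cfg$method
  }
  write_matrix_tsv(psd_norm, file.path(cfg$out_dir, "normalized.tsv"),
                   id_column = "probe_set")
  if (!is.null(report)) {
    slim <- list(
      a1 = if (!is.null(report$a1)) report$a1[c("pass", "median_offdiag",
                                                "mean_offdiag", "threshold")],
      a2 = if (!is.null(report$a2)) list(pass = report$a2$pass,
                                         min_gap = report$a2$min_gap,
                                         max_within_sd =
                                           max(report$a2$within_sd)),
      a3 = if (!is.null(report$a3)) report$a3[c("pass", "covered_fraction",
                                                "max_extrapolation")],
      fallback_used = report$fallback_used, method_used = method_used)
    jsonlite::write_json(slim, file.path(cfg$out_dir, "assumptions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(correction))
    write_correction_tsv(correction,
                         file.path(cfg$out_dir, "correction_knots.tsv"))
  detection <- NULL
  if (cfg$detection == "exiqon") {
    detection <- detection_call_exiqon(pld)
    utils::write.table(
      data.frame(probe_set = rownames(detection),
                 ifelse(detection, "present", "absent"),
                 check.names = FALSE),
      file.path(cfg$out_dir, "detection.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  cvr <- cv_report(pld, psd_norm, design, detection = detection)
  write_cv_report(cvr, cfg$out_dir)
  de <- NULL
  if (isTRUE(cfg$de$enabled)) {
    de <- fit_dose_response(psd_norm, design)
    utils::write.table(
      format(de, digits = 15, scientific = TRUE, trim = TRUE),
      file.path(cfg$out_dir, "de_results.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$de$pairwise)) {
      pw <- pairwise_log2fc(psd_norm, design, cfg$de$pairwise[1],
                            cfg$de$pairwise[2])
      utils::write.table(
        format(pw, digits = 15, scientific = TRUE, trim = TRUE),
        file.path(cfg$out_dir, "pairwise_log2fc.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(probesets = psd_norm, report = report,
                 correction = correction, detection = detection,
                 cv = cvr, de = de, method_used = method_used,
                 design = design))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic fixture), `normalize`, `qc`,
#' `de` and `run` (all stages). All subcommands other than `simulate` are
#' thin wrappers around [run_pipeline()] with the other stages disabled.
#' Invoke from a shell via the installed wrapper script
#' `system.file("cli", "spikenorm.R", package = "spikenorm")`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
spikenorm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: spikenorm.R <simulate|normalize|qc|de|run> [options]",
    "  --config FILE   pipeline config (JSON or YAML)",
    "  --input DIR     fixture directory (ImaGene files + annotation/design)",
    "  --method NAME   scn | median | quantile",
    "  --out DIR       output directory",
    "  --seed INT      random seed", sep = "\n")
  if (!length(args) ||
      !args[1] %in% c("simulate", "normalize", "qc", "de", "run")) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- args[-1]
  get_opt <- function(flag, default = NULL) {
    i <- which(opts == flag)
    if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
  }
  status <- tryCatch({
    cfg <- if (!is.null(get_opt("--config")))
      read_pipeline_config(get_opt("--config")) else pipeline_config()
    if (!is.null(get_opt("--input"))) cfg$input <- get_opt("--input")
    if (!is.null(get_opt("--method"))) cfg$method <- get_opt("--method")
    if (!is.null(get_opt("--out"))) cfg$out_dir <- get_opt("--out")
    if (!is.null(get_opt("--seed")))
      cfg$seed <- as.integer(get_opt("--seed"))
    cfg <- do.call(pipeline_config, unclass(cfg))
    if (sub == "simulate") {
      sim_cfg <- do.call(simulation_config,
                         c(cfg$simulate, list(seed = cfg$seed)))
      write_fixture(simulate_experiment(sim_cfg), cfg$out_dir)
    } else {
      if (sub == "normalize") {
        cfg$detection <- "none"; cfg$de$enabled <- FALSE
      } else if (sub == "qc") cfg$de$enabled <- FALSE
      run_pipeline(cfg)
    }
    0L
  }, error = function(e) {
    message("[", sub, "] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
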