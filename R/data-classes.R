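#' Probe-level intensity data
#'
#' Container for log2 probe-by-array intensities together with per-probe
#' quality flags and the probe annotation that assigns every probe to a
#' probe set and a probe class (`"mirna"`, `"spikein"` or `"other"`).
#'
#' All downstream computation works on the log2 scale; importers are
#' responsible for the linear-to-log2 transform (with a floor of 1 on the
#' linear scale so no value is non-finite).
#'
#' @param intensities numeric matrix of log2 intensities; rownames are probe
#'   ids, colnames are array labels. At least 2 arrays (the normalization is
#'   multi-array by construction).
#' @param annotation data.frame with columns `probe`, `probe_set`,
#'   `probe_class` (and optionally `species`); one row per probe of
#'   `intensities`.
#' @param flags logical matrix of the same shape as `intensities`;
#'   `TRUE` marks a "bad quality" probe measurement. Defaults to all-`FALSE`.
#' @param channel scanned channel tag, one of `"Hy3"`, `"Hy5"`, `"single"`.
#'
#' @return an object of class `ProbeLevelData` with elements `intensities`,
#'   `flags`, `annotation`, `channel`.
#' @export
probe_level_data <- function(intensities, annotation, flags = NULL,
                             channel = "single") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)))
    stop("intensities must have probe ids as rownames")
  if (is.null(colnames(intensities)))
    stop("intensities must have array labels as colnames")
  if (is.null(flags)) {
    flags <- matrix(FALSE, nrow(intensities), ncol(intensities),
                    dimnames = dimnames(intensities))
  }
  flags <- as.matrix(flags)
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  obj <- structure(
    list(intensities = intensities, flags = flags,
         annotation = annotation, channel = channel),
    class = "ProbeLevelData")
  validate_probe_level_data(obj)
  obj
}

validate_probe_level_data <- function(x) {
  E <- x$intensities
  if (ncol(E) < 2)
    stop("ProbeLevelData requires at least 2 arrays (multi-array method)")
  if (!all(is.finite(E)))
    stop("ProbeLevelData intensities must be finite; the importer must ",
         "resolve missing values (default: error)")
  if (!identical(dim(x$flags), dim(E)))
    stop("flags matrix must have the same shape as intensities")
  ann <- x$annotation
  req <- c("probe", "probe_set", "probe_class")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe))
    stop("annotation assigns some probe to more than one probe set: ",
         paste(unique(ann$probe[duplicated(ann$probe)]), collapse = ", "))
  unknown <- setdiff(rownames(E), ann$probe)
  if (length(unknown))
    stop("probes absent from annotation: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  bad_class <- setdiff(unique(ann$probe_class), c("mirna", "spikein", "other"))
  if (length(bad_class))
    stop("unknown probe_class value(s): ", paste(bad_class, collapse = ", "))
  invisible(x)
}

#' @export
print.ProbeLevelData <- function(x, ...) {
  ann <- x$annotation[match(rownames(x$intensities), x$annotation$probe), ]
  cat(sprintf("ProbeLevelData: %d probes x %d arrays (channel %s)\n",
              nrow(x$intensities), ncol(x$intensities), x$channel))
  cat(sprintf("  probe sets: %d (%d spike-in)\n",
              length(unique(ann$probe_set)),
              length(unique(ann$probe_set[ann$probe_class == "spikein"]))))
  cat(sprintf("  flagged entries: %d\n", sum(x$flags)))
  invisible(x)
}

# annotation rows aligned to the intensity matrix row order
aligned_annotation <- function(pld) {
  pld$annotation[match(rownames(pld$intensities), pld$annotation$probe), ,
                 drop = FALSE]
}

#' Probe-set level summarized data
#'
#' @param intensities numeric matrix indexed by (probe set, array label).
#' @param n_probes named integer vector: probes contributing to each set.
#' @param probe_class optional named character vector giving each probe
#'   set's class (`"mirna"`, `"spikein"`, `"other"`).
#' @param detection optional logical matrix, same shape as `intensities`,
#'   `TRUE` = "present".
#'
#' @return an object of class `ProbeSetData`.
#' @export
probe_set_data <- function(intensities, n_probes, probe_class = NULL,
                           detection = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)))
    stop("intensities must have probe-set ids as rownames")
  n_probes <- n_probes[rownames(intensities)]
  if (any(is.na(n_probes)) || any(n_probes < 1))
    stop("n_probes must cover every probe set with a count >= 1")
  if (!is.null(detection) && !identical(dim(detection), dim(intensities)))
    stop("detection matrix must have the same shape as intensities")
  structure(
    list(intensities = intensities, n_probes = n_probes,
         probe_class = probe_class, detection = detection),
    class = "ProbeSetData")
}

#' @export
print.ProbeSetData <- function(x, ...) {
  cat(sprintf("ProbeSetData: %d probe sets x %d arrays\n",
              nrow(x$intensities), ncol(x$intensities)))
  if (!is.null(x$detection))
    cat(sprintf("  detection calls: %d present / %d total\n",
                sum(x$detection), length(x$detection)))
  invisible(x)
}

#' Experiment design: array-to-group mapping and group doses
#'
#' @param arrays character vector of array labels.
#' @param groups character vector, same length: treatment group of each array.
#' @param doses named numeric vector mapping each group label to its dose
#'   (same units for all groups); the control group must have dose 0.
#' @param control_group label of the control group; defaults to the (unique)
#'   group with dose 0.
#'
#' @return an object of class `ExperimentDesign` with elements `group_of`
#'   (named by array), `dose_of` (named by group), `control_group`,
#'   `group_sizes`.
#' @export
experiment_design <- function(arrays, groups, doses, control_group = NULL) {
  if (length(arrays) != length(groups))
    stop("arrays and groups must have the same length")
  group_of <- stats::setNames(as.character(groups), as.character(arrays))
  if (is.null(names(doses)))
    stop("doses must be a named vector (names = group labels)")
  miss <- setdiff(unique(groups), names(doses))
  if (length(miss))
    stop("doses missing for group(s): ", paste(miss, collapse = ", "))
  if (any(doses < 0)) stop("doses must be non-negative")
  if (is.null(control_group)) {
    zero <- names(doses)[doses == 0]
    if (length(zero) != 1)
      stop("control_group cannot be inferred: ", length(zero),
           " groups have dose 0")
    control_group <- zero
  }
  if (!control_group %in% names(doses))
    stop("control_group '", control_group, "' not among the groups")
  if (doses[[control_group]] != 0)
    stop("dose of the control group must be 0")
  structure(
    list(group_of = group_of, dose_of = doses,
         control_group = control_group,
         group_sizes = table(group_of)),
    class = "ExperimentDesign")
}

#' @export
print.ExperimentDesign <- function(x, ...) {
  cat(sprintf("ExperimentDesign: %d arrays, %d groups (control: %s)\n",
              length(x$group_of), length(x$dose_of), x$control_group))
  for (g in names(x$dose_of))
    cat(sprintf("  %s: dose %g, n = %d\n", g, x$dose_of[[g]],
                sum(x$group_of == g)))
  invisible(x)
}

# check that a design covers the arrays of an expression matrix
check_design_covers <- function(design, array_labels) {
  miss <- setdiff(array_labels, names(design$group_of))
  if (length(miss))
    stop("arrays absent from the experiment design: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

# normalized dose vector D_k for a set of arrays: doses scaled to [0, 1]
# by the maximum dose ("max") or replaced by the ordinal dose level ("ordinal")
dose_vector <- function(design, array_labels,
                        normalization = c("max", "ordinal")) {
  normalization <- match.arg(normalization)
  check_design_covers(design, array_labels)
  d <- design$dose_of[design$group_of[array_labels]]
  if (normalization == "max") {
    m <- max(d)
    if (m == 0) stop("all doses are zero; no dose response can be fitted")
    d <- d / m
  } else {
    d <- match(d, sort(unique(design$dose_of))) - 1
  }
  stats::setNames(as.numeric(d), array_labels)
}
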