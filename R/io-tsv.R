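#' Read a generic probe-by-array TSV matrix
#'
#' First column = probe ids, remaining columns = arrays. Values are assumed
#' log2 already unless the file starts with a `# scale: linear` directive
#' line, in which case they are floored at 1 and log2-transformed.
#'
#' @param path matrix TSV path.
#' @param annotation_path annotation TSV path (columns `probe`, `probe_set`,
#'   `probe_class`), or a data.frame.
#' @param channel channel tag for the returned object.
#' @return a [probe_level_data()] object (flags all `FALSE`).
#' @export
read_matrix_tsv <- function(path, annotation_path, channel = "single") {
  lines <- readLines(path)
  directive <- grepl("^#", lines)
  linear <- any(grepl("^#\\s*scale:\\s*linear\\s*$", lines[directive]))
  tab <- utils::read.delim(text = lines[!directive], check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("format error: duplicate probe ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  E <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(E) <- "double"
  rownames(E) <- ids
  if (linear) E <- log2(pmax(E, 1))
  ann <- if (is.character(annotation_path) && length(annotation_path) == 1)
    read_annotation_tsv(annotation_path) else
    as.data.frame(annotation_path, stringsAsFactors = FALSE)
  miss <- setdiff(ids, ann$probe)
  if (length(miss))
    stop("annotation error: probes absent from annotation: ",
         paste(utils::head(miss, 10), collapse = ", "))
  probe_level_data(E, ann, channel = channel)
}

#' Write an intensity matrix as TSV with round-trip-safe precision
#'
#' Accepts a `ProbeLevelData`, a `ProbeSetData` or a bare matrix. Labels
#' (including any containing spaces) are written verbatim.
#'
#' @param data object to write.
#' @param path output path.
#' @param id_column header name of the id column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(data, path, id_column = "id") {
  E <- if (is.matrix(data)) data else data$intensities
  header <- paste(c(id_column, colnames(E)), collapse = "\t")
  if (nrow(E)) {
    vals <- apply(E, 1, function(r)
      paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = "\t"))
    body <- paste(rownames(E), vals, sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv_raw <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  E <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(E) <- "double"
  rownames(E) <- as.character(tab[[1]])
  E
}

#' Read a probe annotation TSV (columns: probe, probe_set, probe_class)
#' @param path annotation TSV path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe", "probe_set", "probe_class")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  ann
}

#' Read an experiment design TSV (columns: array, group, dose[, is_control])
#' @param path design TSV path.
#' @return an [experiment_design()] object.
#' @export
read_design_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("array", "group", "dose")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("design TSV missing column(s): ", paste(miss, collapse = ", "))
  doses <- tapply(tab$dose, tab$group, function(d) {
    if (length(unique(d)) != 1)
      stop("design TSV: inconsistent doses within a group")
    d[1]
  })
  ctrl <- NULL
  if ("is_control" %in% names(tab)) {
    ctrl <- unique(tab$group[as.logical(tab$is_control)])
    if (length(ctrl) != 1)
      stop("design TSV must mark exactly one control group")
  }
  experiment_design(tab$array, tab$group,
                    stats::setNames(as.numeric(doses), names(doses)),
                    control_group = ctrl)
}

#' Write an experiment design TSV
#' @param design an [experiment_design()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_design_tsv <- function(design, path) {
  tab <- data.frame(
    array = names(design$group_of),
    group = unname(design$group_of),
    dose = unname(design$dose_of[design$group_of]),
    is_control = unname(design$group_of == design$control_group))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-summarize probes into probe sets
#'
#' Each (probe set, array) entry is the median of the log2 intensities of
#' the probes mapping to that set on that array. Flags are deliberately
#' ignored here: they feed the detection calls, not the summarization.
#'
#' @param pld a [probe_level_data()] object.
#' @return a [probe_set_data()] object; probe-set class is carried over
#'   from the member probes.
#' @export
summarize_probesets <- function(pld) {
  ann <- aligned_annotation(pld)
  sets <- unique(ann$probe_set)
  idx <- split(seq_len(nrow(pld$intensities)), ann$probe_set)[sets]
  E <- t(vapply(idx, function(i)
    apply(pld$intensities[i, , drop = FALSE], 2, stats::median),
    numeric(ncol(pld$intensities))))
  colnames(E) <- colnames(pld$intensities)
  n_probes <- vapply(idx, length, 0L)
  cls <- vapply(idx, function(i) ann$probe_class[i[1]], "")
  probe_set_data(E, n_probes, probe_class = cls)
}
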