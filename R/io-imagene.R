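#' Read ImaGene-dialect probe-level text exports
#'
#' Parses a minimal ImaGene 8.0-style dialect: a tab-delimited block between
#' `Begin Raw Data` and `End Raw Data` lines, with a header row containing at
#' least the columns `Gene ID`, `Signal Median`, `Background Median` and
#' `Flag`. One file per array (the sample channel of a common-reference
#' dual-channel design is treated as pseudo-single-channel data; the
#' reference channel is simply never imported).
#'
#' Signal values are linear scanner units; they are floored at 1 and log2
#' transformed at import. Any nonzero `Flag` value marks the probe
#' measurement as bad quality (configurable via `bad_flag`).
#'
#' @param paths character vector of file paths, one per array; array labels
#'   are taken from `names(paths)` or from the file basenames.
#' @param annotation probe annotation: a data.frame with columns `probe`,
#'   `probe_set`, `probe_class`, or a path to an annotation TSV.
#' @param channel channel tag recorded on the returned object.
#' @param background `"none"` (log2 of the floored signal) or `"subtract"`
#'   (background median subtracted on the linear scale, floored at 1,
#'   then log2).
#' @param bad_flag function mapping the numeric flag column to a logical
#'   bad-quality indicator; default: any nonzero flag is bad.
#' @param missing what to do with missing signal entries: `"error"`
#'   (default) or `"impute"` with the array median (computed on log2 scale).
#'
#' @return a [probe_level_data()] object.
#' @export
read_imagene <- function(paths, annotation, channel = "Hy3",
                         background = c("none", "subtract"),
                         bad_flag = function(f) f != 0,
                         missing = c("error", "impute")) {
  background <- match.arg(background)
  missing <- match.arg(missing)
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- read_annotation_tsv(annotation)
  labels <- names(paths)
  if (is.null(labels))
    labels <- sub("\\.[^.]*$", "", basename(paths))
  parsed <- lapply(paths, parse_imagene_file)
  roster <- parsed[[1]]$`Gene ID`
  for (i in seq_along(parsed)) {
    ids <- parsed[[i]]$`Gene ID`
    if (!setequal(ids, roster) || anyDuplicated(ids)) {
      off <- union(setdiff(ids, roster), setdiff(roster, ids))
      if (!length(off)) off <- unique(ids[duplicated(ids)])
      stop("probe rosters differ across files (", paths[i],
           "); offending probes: ", paste(utils::head(off, 10), collapse = ", "))
    }
  }
  K <- length(parsed)
  E <- matrix(NA_real_, length(roster), K, dimnames = list(roster, labels))
  FL <- matrix(FALSE, length(roster), K, dimnames = list(roster, labels))
  for (i in seq_len(K)) {
    d <- parsed[[i]]
    d <- d[match(roster, d$`Gene ID`), ]
    sig <- d$`Signal Median`
    if (background == "subtract") sig <- sig - d$`Background Median`
    E[, i] <- log2(pmax(sig, 1))
    FL[, i] <- bad_flag(d$Flag)
    if (anyNA(E[, i])) {
      if (missing == "error")
        stop("missing signal values in ", paths[i],
             " (probes: ", paste(utils::head(roster[is.na(E[, i])], 5),
                                 collapse = ", "), ")")
      E[is.na(E[, i]), i] <- stats::median(E[, i], na.rm = TRUE)
    }
  }
  probe_level_data(E, annotation, flags = FL, channel = channel)
}

# parse one ImaGene-dialect file into a data.frame with the required columns
parse_imagene_file <- function(path) {
  lines <- readLines(path)
  beg <- which(trimws(lines) == "Begin Raw Data")
  end <- which(trimws(lines) == "End Raw Data")
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("format error in ", path,
         ": expected one 'Begin Raw Data' ... 'End Raw Data' block")
  block <- lines[(beg + 1):(end - 1)]
  header <- strsplit(block[1], "\t", fixed = TRUE)[[1]]
  required <- c("Gene ID", "Signal Median", "Background Median", "Flag")
  miss <- setdiff(required, header)
  if (length(miss))
    stop("format error in ", path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  rows <- strsplit(block[-1], "\t", fixed = TRUE)
  n <- length(rows)
  get_col <- function(name) vapply(rows, function(r) r[match(name, header)], "")
  out <- data.frame(`Gene ID` = get_col("Gene ID"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("Signal Median", "Background Median", "Flag")) {
    raw <- get_col(col)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad))
      stop("parse error in ", path, ": non-numeric '", col, "' at line ",
           beg + 1 + bad[1], " ('", raw[bad[1]], "')")
    out[[col]] <- val
  }
  out
}

#' Write probe-level data as ImaGene-dialect files (one per array)
#'
#' Intended for building text fixtures that round-trip through
#' [read_imagene()]. Linear signal values `2^E` are written with enough
#' digits to reproduce the log2 matrix to better than 1e-9.
#'
#' @param pld a [probe_level_data()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_imagene <- function(pld, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- colnames(pld$intensities)
  paths <- stats::setNames(file.path(dir, paste0(labels, ".txt")), labels)
  for (k in seq_along(labels)) {
    sig <- format(2^pld$intensities[, k], digits = 17, scientific = FALSE,
                  trim = TRUE)
    body <- paste(rownames(pld$intensities), sig, "0",
                  as.integer(pld$flags[, k]), sep = "\t")
    writeLines(c("ImaGene export (synthetic fixture)",
                 "Begin Raw Data",
                 "Gene ID\tSignal Median\tBackground Median\tFlag",
                 body,
                 "End Raw Data"),
               paths[k])
  }
  invisible(paths)
}
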