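#' MEDIAN normalization
#'
#' Subtracts each array's median intensity and re-centers to the grand
#' median (the median of the per-array medians), so every array ends up
#' with the same median while the absolute log2 scale stays comparable to
#' the raw data. This is the fallback normalization used when the SCN
#' applicability checks fail; SCN with a constant (intensity-independent)
#' correction function reduces to it.
#'
#' @param data a [probe_level_data()], [probe_set_data()] or bare matrix.
#' @return same type, normalized.
#' @export
median_normalize <- function(data) {
  E <- if (is.matrix(data)) data else data$intensities
  med <- apply(E, 2, stats::median)
  E <- sweep(E, 2, med) + stats::median(med)
  if (is.matrix(data)) return(E)
  data$intensities <- E
  data
}

#' Quantile normalization
#'
#' Classic quantile normalization: each array's sorted values are replaced
#' by the across-array mean of the sorted columns; tied values receive the
#' mean of the reference values their ranks span. Forces an identical
#' intensity distribution on every array, which is exactly the assumption
#' a dataset with a global decrease in expression violates.
#'
#' @param data a [probe_level_data()], [probe_set_data()] or bare matrix.
#' @return same type, normalized.
#' @export
quantile_normalize <- function(data) {
  E <- if (is.matrix(data)) data else data$intensities
  if (ncol(E) < 2) stop("quantile normalization needs at least 2 arrays")
  ref <- rowMeans(apply(E, 2, sort))
  out <- E
  for (k in seq_len(ncol(E))) {
    r <- rank(E[, k], ties.method = "average")
    out[, k] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  if (is.matrix(data)) return(out)
  data$intensities <- out
  data
}
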