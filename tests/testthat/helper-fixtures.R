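# Small in-code fixtures shared across test files.

# probe-level data with explicit values: one probe set per row-group
make_pld <- function(E, probe_set, probe_class, flags = NULL,
                     channel = "single") {
  ann <- data.frame(probe = rownames(E), probe_set = probe_set,
                    probe_class = probe_class, stringsAsFactors = FALSE)
  probe_level_data(E, ann, flags = flags, channel = channel)
}

# K-array, J-set probe-set matrix with labelled dims
make_psd <- function(E, n_probes = NULL, probe_class = NULL) {
  if (is.null(n_probes))
    n_probes <- stats::setNames(rep(1L, nrow(E)), rownames(E))
  probe_set_data(E, n_probes, probe_class = probe_class)
}

# standard 4-group x n design over the columns of a matrix
make_design <- function(arrays, n_groups = 4,
                        doses = c(sham = 0, low = 75, medium = 150,
                                  high = 300)) {
  per <- length(arrays) / n_groups
  experiment_design(arrays, rep(names(doses)[seq_len(n_groups)], each = per),
                    doses[seq_len(n_groups)])
}

# SpikeInMatrix built directly from a probe-set matrix (one probe per set)
make_spikein <- function(values, probe_level = NULL, set_of_probe = NULL) {
  if (is.null(probe_level)) {
    probe_level <- values
    rownames(probe_level) <- paste0(rownames(values), "_p1")
    set_of_probe <- stats::setNames(rownames(values),
                                    rownames(probe_level))
  }
  structure(list(values = values, row_means = rowMeans(values),
                 probe_level = probe_level,
                 probe_set_of_probe = set_of_probe),
            class = "SpikeInMatrix")
}

# independent piecewise-linear-with-clamping oracle used against
# predict.CorrectionFunction and apply_correction
interp_oracle <- function(xk, yk, x) {
  vapply(x, function(v) {
    if (v <= xk[1]) return(yk[1])
    n <- length(xk)
    if (v >= xk[n]) return(yk[n])
    i <- max(which(xk <= v))
    if (xk[i] == v) return(yk[i])
    yk[i] + (yk[i + 1] - yk[i]) * (v - xk[i]) / (xk[i + 1] - xk[i])
  }, 0)
}

# brute-force one-sided rank-sum p-value by full enumeration
rank_sum_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(m + n, m)
  mean(apply(combos, 2, function(idx) sum(r[idx])) >= w_obs - 1e-9)
}
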