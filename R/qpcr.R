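#' Comparative-Ct RT-qPCR differential expression
#'
#' Standard comparative-Ct processing: technical-triplicate Ct values are
#' averaged per (miRNA, sample); `dCt = Ct(target) - Ct(endogenous
#' control)` per sample; the per-miRNA differential expression between a
#' treated and a control group is the group difference of mean dCt, with a
#' pooled two-sample t-test across samples for significance.
#'
#' Sign convention: one extra PCR cycle means half the template, so a
#' *higher* Ct in the treated group means *lower* expression. The default
#' `"down_negative"` computes `mean dCt(control group) - mean dCt(treated
#' group)`, making down-regulation negative (log2 fold change scale:
#' `2^value` is the fold change). `"as_printed"` computes the mirrored
#' `mean dCt(treated) - mean dCt(control)`.
#'
#' @param qpcr data.frame with columns `mirna`, `sample`, `ct` and
#'   optionally `replicate` (long format, one row per technical replicate).
#' @param groups named character vector mapping sample -> group, or an
#'   [experiment_design()] whose array labels are the sample names.
#' @param comparison character pair `c(treated, control)` of group labels.
#' @param endogenous_control name (in `mirna`) of the endogenous control
#'   gene, e.g. a small nucleolar RNA.
#' @param sign_convention `"down_negative"` (default) or `"as_printed"`.
#' @return data.frame: `mirna`, `minus_ddct`, `p.value`, `n_treated`,
#'   `n_control`.
#' @export
comparative_ct <- function(qpcr, groups, comparison,
                           endogenous_control = "sno135",
                           sign_convention = c("down_negative",
                                               "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  if (inherits(groups, "ExperimentDesign")) groups <- groups$group_of
  req <- c("mirna", "sample", "ct")
  miss <- setdiff(req, names(qpcr))
  if (length(miss))
    stop("qpcr table missing column(s): ", paste(miss, collapse = ", "))
  # average the technical replicates first
  mean_ct <- stats::aggregate(ct ~ mirna + sample, data = qpcr, FUN = mean)
  ctrl_ct <- mean_ct[mean_ct$mirna == endogenous_control, ]
  if (!nrow(ctrl_ct))
    stop("endogenous control '", endogenous_control, "' absent from table")
  targets <- setdiff(unique(mean_ct$mirna), endogenous_control)
  treated_samples <- names(groups)[groups == comparison[1]]
  control_samples <- names(groups)[groups == comparison[2]]
  out <- lapply(targets, function(m) {
    tgt <- mean_ct[mean_ct$mirna == m, ]
    samples <- tgt$sample
    ctl <- ctrl_ct$ct[match(samples, ctrl_ct$sample)]
    if (anyNA(ctl))
      stop("endogenous control Ct missing for sample(s): ",
           paste(samples[is.na(ctl)], collapse = ", "))
    dct <- stats::setNames(tgt$ct - ctl, samples)
    a <- dct[intersect(samples, treated_samples)]
    b <- dct[intersect(samples, control_samples)]
    if (length(a) < 2 || length(b) < 2)
      stop("comparative_ct needs >= 2 samples per group for ", m)
    val <- if (sign_convention == "down_negative")
      mean(b) - mean(a) else mean(a) - mean(b)
    # pooled two-sample t; degenerate zero-variance cases handled explicitly
    df <- length(a) + length(b) - 2
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    p <- if (se == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else 2 * stats::pt(-abs((mean(a) - mean(b)) / se), df = df)
    data.frame(mirna = m, minus_ddct = val, p.value = p,
               n_treated = length(a), n_control = length(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read an RT-qPCR Ct table (columns: mirna, sample, replicate, ct)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_qpcr_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("mirna", "sample", "ct"), names(tab))
  if (length(miss))
    stop("qPCR TSV missing column(s): ", paste(miss, collapse = ", "))
  tab
}
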