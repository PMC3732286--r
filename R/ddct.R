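# Relative quantification of qPCR expression by the delta-delta Ct
# method with a multi-gene reference, case/control fold changes with
# direction, group tests and Bonferroni correction.

#' Per-sample reference value from control-gene Ct values
#'
#' The arithmetic mean of the sample's reference-gene Ct values, which
#' on the quantity scale equals the geometric mean of the reference
#' quantities 2^-Ct.
#'
#' @param ct numeric Ct values of the reference genes in one sample.
#' @return the reference Ct (cycles).
#' @examples
#' reference_value(c(20, 22, 24))  # 22
#' @export
reference_value <- function(ct) {
  ct <- ct[!is.na(ct)]
  if (!length(ct)) stop("no reference gene measured")
  mean(ct)
}

#' Relative quantity from Ct values
#'
#' `RQ = 2^-(target Ct - reference Ct)`; shifting both Ct values by a
#' constant leaves the quantity unchanged.
#'
#' @param target_ct,reference_ct cycle thresholds.
#' @return the relative quantity.
#' @examples
#' relative_quantity(25, 20)  # 1/32
#' @export
relative_quantity <- function(target_ct, reference_ct) {
  2^-(target_ct - reference_ct)
}

#' Fold change between case and control quantities
#'
#' The ratio of group mean relative quantities, reported as a magnitude
#' of at least 1 with the direction of regulation in cases relative to
#' controls (a ratio of exactly 1 is reported as `UP`).
#'
#' @param case_rq,control_rq relative quantities per group.
#' @return list with `fold_change` (>= 1) and `direction`
#'   (`"UP"`/`"DOWN"`).
#' @export
fold_change <- function(case_rq, control_rq) {
  r <- mean(case_rq, na.rm = TRUE) / mean(control_rq, na.rm = TRUE)
  if (r >= 1) list(fold_change = r, direction = "UP")
  else list(fold_change = 1 / r, direction = "DOWN")
}

#' Group test on delta-Ct values
#'
#' Two-sided Welch t-test (default) or Mann-Whitney test comparing case
#' and control delta-Ct values for one assay.
#'
#' @param case_dct,control_dct delta-Ct values.
#' @param test `"welch"` or `"mannwhitney"`.
#' @return the p-value, `NA` when either group has fewer than two
#'   values or no variation supports a test.
#' @export
group_test <- function(case_dct, control_dct, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  case_dct <- case_dct[!is.na(case_dct)]
  control_dct <- control_dct[!is.na(control_dct)]
  if (length(case_dct) < 2L || length(control_dct) < 2L) return(NA_real_)
  if (test == "welch") {
    if (stats::sd(case_dct) == 0 && stats::sd(control_dct) == 0) {
      return(if (mean(case_dct) == mean(control_dct)) 1 else NA_real_)
    }
    stats::t.test(case_dct, control_dct)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(case_dct, control_dct)$p.value)
  }
}

#' Bonferroni correction
#'
#' @param p raw p-values.
#' @param m number of tests.
#' @return `min(1, p * m)`, vectorised.
#' @examples
#' bonferroni(7.55e-6, 38)  # 2.87e-4
#' @export
bonferroni <- function(p, m) {
  pmin(1, p * m)
}

#' Delta-delta Ct expression analysis
#'
#' Computes, for every non-reference assay in a long-format Ct table,
#' the case/control fold change (control mean normalised to 1), the raw
#' group-test p-value on delta-Ct values, and the Bonferroni-corrected
#' p-value.  Samples without any measured reference gene are excluded
#' with a warning.  Assays with no computable p-value (e.g. no detected
#' expression) are reported but excluded from the correction multiplier
#' when `m = "auto"`.
#'
#' @param ct long-format Ct table (`sample`, `group`, `gene`, `assay`,
#'   `ct`); `group` must be `case`/`control`.
#' @param reference_genes gene symbols used as the reference.
#' @param test passed to [group_test()].
#' @param m Bonferroni multiplier, or `"auto"` for the number of assays
#'   with a computed p-value.
#' @return data frame of class `ddct_result`, ordered by raw p-value,
#'   with columns `gene`, `assay`, `n_case`, `n_control`, `fold_change`,
#'   `direction`, `p_raw`, `p_corrected`; the multiplier is attached as
#'   attribute `"m"`.
#' @export
ddct_analysis <- function(ct, reference_genes = c("ACTB", "EPCAM", "PGK1"),
                          test = c("welch", "mannwhitney"), m = "auto") {
  test <- match.arg(test)
  stopifnot(all(c("sample", "group", "gene", "assay", "ct") %in% names(ct)))
  is_ref <- ct$gene %in% reference_genes
  ref_by_sample <- tapply(ct$ct[is_ref], ct$sample[is_ref],
                          function(v) if (all(is.na(v))) NA_real_ else reference_value(v))
  samples <- unique(ct$sample)
  no_ref <- samples[!samples %in% names(ref_by_sample) |
                      is.na(ref_by_sample[samples])]
  if (length(no_ref)) {
    warning(length(no_ref), " sample(s) without a reference gene excluded: ",
            paste(utils::head(no_ref, 5L), collapse = ", "))
  }
  tgt <- ct[!is_ref & !ct$sample %in% no_ref, , drop = FALSE]
  tgt$dct <- tgt$ct - unname(ref_by_sample[tgt$sample])
  tgt$rq <- 2^-tgt$dct
  assays <- unique(tgt[, c("gene", "assay")])
  rows <- lapply(seq_len(nrow(assays)), function(i) {
    a <- tgt[tgt$assay == assays$assay[i] & !is.na(tgt$ct), , drop = FALSE]
    case <- a[a$group == "case", , drop = FALSE]
    ctrl <- a[a$group == "control", , drop = FALSE]
    fc <- if (nrow(case) && nrow(ctrl)) fold_change(case$rq, ctrl$rq)
          else list(fold_change = NA_real_, direction = NA_character_)
    data.frame(gene = assays$gene[i], assay = assays$assay[i],
               n_case = nrow(case), n_control = nrow(ctrl),
               fold_change = fc$fold_change, direction = fc$direction,
               p_raw = group_test(case$dct, ctrl$dct, test),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m_val <- if (identical(m, "auto")) sum(!is.na(out$p_raw)) else m
  out$p_corrected <- bonferroni(out$p_raw, m_val)
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m_val
  class(out) <- c("ddct_result", "data.frame")
  out
}

#' Strip-plot of relative quantities by group
#'
#' Plots per-sample relative quantities for one assay, with the control
#' group mean normalised to 1.
#'
#' @param x a `ddct_result` (used for labelling) or ignored.
#' @param ct the long-format Ct table the result came from.
#' @param assay assay id to plot.
#' @param reference_genes reference genes (as in [ddct_analysis()]).
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.ddct_result <- function(x, ct, assay = x$assay[1L],
                             reference_genes = c("ACTB", "EPCAM", "PGK1"), ...) {
  is_ref <- ct$gene %in% reference_genes
  ref_by_sample <- tapply(ct$ct[is_ref], ct$sample[is_ref], reference_value)
  a <- ct[ct$assay == assay & !is.na(ct$ct), , drop = FALSE]
  rq <- 2^-(a$ct - unname(ref_by_sample[a$sample]))
  rq <- rq / mean(rq[a$group == "control"])
  graphics::stripchart(split(rq, a$group), vertical = TRUE, method = "jitter",
                       pch = 1, ylab = "relative expression (control mean = 1)",
                       main = assay, ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
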