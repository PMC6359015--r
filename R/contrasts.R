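#' The four canonical comparisons
#'
#' Two "vertical" within-genotype contrasts (flight vs ground, defining each
#' genotype's physiological adaptation) and two "horizontal" within-
#' environment contrasts (knockout vs wild type, defining the adapted-state
#' genotype difference). Each label reads `first_vs_second`: the log2 fold
#' change is mean(first) - mean(second).
#'
#' @return Character vector of the four comparison labels.
#' @export
de_comparisons <- function() {
  c("FWt_vs_GWt", "FHsf_vs_GHsf", "GHsf_vs_GWt", "FHsf_vs_FWt")
}

comparison_cells <- function(comparison) {
  switch(comparison,
    FWt_vs_GWt   = c("WT.flight", "WT.ground"),
    FHsf_vs_GHsf = c("KO.flight", "KO.ground"),
    GHsf_vs_GWt  = c("KO.ground", "WT.ground"),
    FHsf_vs_FWt  = c("KO.flight", "WT.flight"),
    stop("unknown comparison: '", comparison, "' (expected one of ",
         paste(de_comparisons(), collapse = ", "), ")", call. = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, multiplies by m/rank, takes cumulative minima
#' from the largest rank downward, caps at 1, and returns the adjusted values
#' in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1L)))[ro]
}

#' Moderated t-test for one comparison
#'
#' Computes, per gene, the log2 fold change between the two cells named by
#' the comparison, the moderated t-statistic `log2FC / sqrt(s2_post (1/n1 +
#' 1/n2))`, the two-sided p-value on d_g + d0 degrees of freedom (standard
#' normal when d0 is infinite), and the BH-adjusted p-value.
#'
#' @param fit a [de_fit()].
#' @param comparison one of [de_comparisons()].
#' @return A data.frame of class `"de_contrast"` with columns `gene_id`,
#'   `log2FC`, `t_mod`, `p_raw`, `p_adj`, and attribute `comparison`.
#' @export
contrast_test <- function(fit, comparison) {
  stopifnot(inherits(fit, "de_fit"))
  cl <- comparison_cells(comparison)
  lfc <- fit$means[, cl[1L]] - fit$means[, cl[2L]]
  se <- sqrt(fit$s2_post * (1 / fit$n[[cl[1L]]] + 1 / fit$n[[cl[2L]]]))
  t_mod <- ifelse(lfc == 0, 0, lfc / se)
  p_raw <- ifelse(lfc == 0, 1,
                  2 * stats::pt(-abs(t_mod), df = fit$df_total))
  res <- data.frame(gene_id = fit$gene_ids, log2FC = unname(lfc),
                    t_mod = unname(t_mod), p_raw = unname(p_raw),
                    p_adj = bh_adjust(unname(p_raw)))
  rownames(res) <- NULL
  attr(res, "comparison") <- comparison
  attr(res, "df_total") <- fit$df_total
  class(res) <- c("de_contrast", "data.frame")
  res
}

#' @export
print.de_contrast <- function(x, ...) {
  cat(sprintf("de_contrast '%s': %d genes (df = %s)\n",
              attr(x, "comparison"), nrow(x),
              format(attr(x, "df_total"), digits = 4)))
  if ("status" %in% names(x))
    print(table(status = x$status))
  print(utils::head(as.data.frame(x)[order(x$p_raw), ], 6L))
  invisible(x)
}

#' Significance thresholds for differential-expression calls
#'
#' Defaults mirror the stringent criteria used throughout: p-value below
#' 0.01 and absolute fold change above 2 (|log2FC| > 1), applied to the
#' BH-adjusted p-value.
#'
#' @param p_threshold strict upper bound on the p-value (0 < p < 1).
#' @param lfc_threshold strict lower bound on |log2FC| (>= 0).
#' @param use_adjusted_p gate on BH-adjusted (`TRUE`, default) or raw p.
#' @return A list of class `"threshold_config"`.
#' @export
threshold_config <- function(p_threshold = 0.01, lfc_threshold = 1,
                             use_adjusted_p = TRUE) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop("'p_threshold' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(lfc_threshold) || lfc_threshold < 0)
    stop("'lfc_threshold' must be >= 0", call. = FALSE)
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                 use_adjusted_p = isTRUE(use_adjusted_p)),
            class = "threshold_config")
}

#' Call differential expression
#'
#' A gene is significant iff its chosen p-value is strictly below
#' `p_threshold` and |log2FC| strictly exceeds `lfc_threshold`; the direction
#' (`up`/`down`) follows the sign of the fold change, all other genes are
#' `ns`.
#'
#' @param result a [contrast_test()] result.
#' @param thresholds a [threshold_config()].
#' @return `result` with an added `status` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_de <- function(result, thresholds = threshold_config()) {
  stopifnot(inherits(result, "de_contrast"),
            inherits(thresholds, "threshold_config"))
  p <- if (thresholds$use_adjusted_p) result$p_adj else result$p_raw
  sig <- p < thresholds$p_threshold &
    abs(result$log2FC) > thresholds$lfc_threshold
  result$status <- ifelse(!sig, "ns", ifelse(result$log2FC > 0, "up", "down"))
  result
}

#' Write a per-comparison results table
#'
#' @param result a [contrast_test()] result, usually after [call_de()].
#' @param path output TSV path.
#' @return `result`, invisibly.
#' @export
write_contrast <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}
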