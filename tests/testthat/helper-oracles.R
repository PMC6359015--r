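# Independent oracles, deliberately coded along different routes than the
# package internals.

# Literal rule-checker for the cross-contrast taxonomy: evaluates each
# category's criteria list verbatim against one 4-tuple and applies the
# documented precedence.
oracle_classify <- function(pattern) {
  stopifnot(length(pattern) == 4L)
  v_wt <- pattern[1L]; v_ko <- pattern[2L]   # vertical: flight vs ground
  h_g <- pattern[3L];  h_f <- pattern[4L]    # horizontal: KO vs WT
  is_sig <- function(s) s %in% c("up", "down")
  matches <- character(0L)
  if (is_sig(v_wt) && is_sig(v_ko) && v_wt == v_ko)
    matches <- c(matches, "shared_same")
  if (is_sig(v_wt) && is_sig(v_ko) && v_wt != v_ko)
    matches <- c(matches, "shared_opposite")
  if (is_sig(v_wt) && v_ko == "ns" && is_sig(h_g) && h_f == "ns")
    matches <- c(matches, "required")
  if (v_wt == "ns" && is_sig(v_ko) && is_sig(h_g) && h_f == "ns")
    matches <- c(matches, "corrected")
  if (is_sig(v_wt) && v_ko == "ns" && h_g == "ns" && is_sig(h_f))
    matches <- c(matches, "genotype_dependent")
  if (v_wt == "ns" && is_sig(v_ko) && h_g == "ns" && is_sig(h_f))
    matches <- c(matches, "compensated")
  if (is_sig(h_g) && is_sig(h_f) && h_g == h_f)
    matches <- c(matches, "persistent_genotype_difference")
  precedence <- c("shared_same", "shared_opposite", "required", "corrected",
                  "genotype_dependent", "compensated",
                  "persistent_genotype_difference")
  for (cat in precedence) if (cat %in% matches) return(cat)
  if (all(pattern == "ns")) "none" else "other_pattern"
}

# All 81 possible status 4-tuples.
all_patterns <- function() {
  as.matrix(expand.grid(FWt_vs_GWt = c("up", "down", "ns"),
                        FHsf_vs_GHsf = c("up", "down", "ns"),
                        GHsf_vs_GWt = c("up", "down", "ns"),
                        FHsf_vs_FWt = c("up", "down", "ns"),
                        stringsAsFactors = FALSE))
}

# QR-based linear-model oracle for one gene and one comparison: cell-means
# design via stats::lm, contrast and its SE from vcov(), two-sided p on the
# residual df. Shares no code with the package's closed-form fit.
oracle_lm_contrast <- function(y, meta, cell_a, cell_b) {
  cell <- factor(paste(meta$genotype, meta$environment, sep = "."),
                 levels = c("WT.ground", "WT.flight", "KO.ground",
                            "KO.flight"))
  fit <- stats::lm(y ~ 0 + cell)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  cn <- paste0("cell", levels(cell))
  cvec <- as.numeric(cn == paste0("cell", cell_a)) -
    as.numeric(cn == paste0("cell", cell_b))
  est <- sum(cvec * b)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  tt <- est / se
  c(log2FC = est, t = tt,
    p = 2 * stats::pt(-abs(tt), df = fit$df.residual))
}

# Direct combinatorial-summation oracle for the hypergeometric upper tail
# P(X >= k) when drawing n from N containing K successes.
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small simulated study shared across tests.
default_category_counts <- function(k = 20L) {
  stats::setNames(rep(k, 7L),
                  c("shared_same", "shared_opposite", "required", "corrected",
                    "genotype_dependent", "compensated",
                    "persistent_genotype_difference"))
}

run_classification <- function(sim, thresholds = threshold_config()) {
  fit <- de_fit(sim$expression)
  calls <- lapply(stats::setNames(nm = de_comparisons()),
                  function(cm) call_de(contrast_test(fit, cm), thresholds))
  classify_all(build_comparison_groups(calls))
}
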