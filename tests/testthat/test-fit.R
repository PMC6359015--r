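four_cell_set <- function(values) {
  # 2 samples per cell in the canonical order
  meta <- data.frame(sample_id = colnames(values),
                     genotype = rep(c("WT", "WT", "KO", "KO"), each = 2),
                     environment = rep(c("ground", "flight",
                                         "ground", "flight"), each = 2))
  expression_set(values, meta, scale = "log2")
}

test_that("cell-means fit matches the hand least-squares example", {
  # (WT,ground)=[2,4], (WT,flight)=[6,8], (KO,ground)=[1,3], (KO,flight)=[5,7]
  v <- matrix(c(2, 4, 6, 8, 1, 3, 5, 7), 1, 8,
              dimnames = list("g1", paste0("s", 1:8)))
  fits <- fit_gene_models(four_cell_set(v))
  expect_equal(unname(fits$means[1, ]), c(3, 7, 2, 6))
  expect_identical(colnames(fits$means),
                   c("WT.ground", "WT.flight", "KO.ground", "KO.flight"))
  expect_equal(unname(fits$s2), 2)
  expect_equal(fits$df, 4L)

  # zero-variance gene
  z <- matrix(5, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  expect_equal(unname(fit_gene_models(four_cell_set(z))$s2), 0)

  # shifting one cell moves only that cell's mean (orthogonality)
  v2 <- v; v2[1, 3:4] <- v2[1, 3:4] + 10
  f2 <- fit_gene_models(four_cell_set(v2))
  expect_equal(unname(f2$means[1, "WT.flight"]), 17)
  expect_equal(f2$means[1, c("WT.ground", "KO.ground", "KO.flight")],
               fits$means[1, c("WT.ground", "KO.ground", "KO.flight")])

  # a cell with fewer than 2 samples is rejected
  short <- expression_set(
    v[, 1:7, drop = FALSE],
    data.frame(sample_id = paste0("s", 1:7),
               genotype = c("WT", "WT", "WT", "WT", "KO", "KO", "KO"),
               environment = c("ground", "ground", "flight", "flight",
                               "ground", "ground", "flight")),
    scale = "log2")
  expect_error(fit_gene_models(short), ">= 2 samples")
})

test_that("moderation handles degenerate and limiting cases", {
  # all variances identical -> d0 infinite, posterior equals the common value
  s2 <- rep(0.25, 50)
  mod <- estimate_moderation(s2, df = 12)
  expect_identical(mod$prior_df, Inf)
  expect_equal(mod$prior_var, 0.25, tolerance = 1e-12)
  expect_equal(mod$var_post, rep(0.25, 50))

  # d0 = 0 leaves variances untouched (no-shrinkage limit)
  expect_equal(flightDE:::squeeze_variances(c(1, 2, 3), 4, 0, 10), c(1, 2, 3))

  # posterior always lies weakly between s2 and s0^2
  set.seed(8)
  s2r <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 12) / 12
  modr <- estimate_moderation(s2r, df = 12)
  lo <- pmin(s2r, modr$prior_var); hi <- pmax(s2r, modr$prior_var)
  expect_true(all(modr$var_post >= lo - 1e-12 & modr$var_post <= hi + 1e-12))

  expect_error(estimate_moderation(c(0, 0, 0), 12), "positive")
})

test_that("the variance prior is recovered from simulated data", {
  d0 <- 4; s02 <- 0.05
  sim <- simulate_dataset(simulation_config(n_genes = 10000, seed = 17,
                                            prior_df = d0, prior_var = s02))
  fits <- fit_gene_models(sim$expression)
  mod <- estimate_moderation(fits$s2, fits$df)
  expect_lt(abs(mod$prior_df - d0) / d0, 0.2)
  expect_lt(abs(mod$prior_var - s02) / s02, 0.1)
})

test_that("moderation estimates agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(12)
  sim <- simulate_dataset(simulation_config(n_genes = 3000, seed = 12,
                                            prior_df = 6, prior_var = 0.1))
  fits <- fit_gene_models(sim$expression)
  mod <- estimate_moderation(fits$s2, fits$df)
  sq <- limma::squeezeVar(fits$s2, df = fits$df)
  expect_equal(mod$prior_df, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$prior_var, sq$var.prior, tolerance = 1e-6)
  expect_equal(unname(mod$var_post), unname(sq$var.post), tolerance = 1e-8)
})

test_that("moderated contrasts agree with the limma reference end to end", {
  skip_if_not_installed("limma")
  sim <- simulate_dataset(simulation_config(
    n_genes = 500, seed = 21, prior_df = 5, prior_var = 0.06,
    category_counts = c(required = 20, corrected = 20)))
  x <- sim$expression
  fit <- de_fit(x)

  key <- flightDE:::group_keys(x$meta)
  design <- stats::model.matrix(~ 0 + key)
  colnames(design) <- levels(key)
  lfit <- limma::lmFit(x$values, design)
  cm <- limma::makeContrasts(
    FWt_vs_GWt = WT.flight - WT.ground,
    FHsf_vs_GHsf = KO.flight - KO.ground,
    GHsf_vs_GWt = KO.ground - WT.ground,
    FHsf_vs_FWt = KO.flight - WT.flight,
    levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(lfit, cm))

  expect_equal(fit$prior_df, eb$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior_var, eb$s2.prior, tolerance = 1e-6)
  for (cmp in de_comparisons()) {
    res <- contrast_test(fit, cmp)
    expect_equal(res$log2FC, unname(eb$coefficients[, cmp]),
                 tolerance = 1e-10)
    expect_equal(res$t_mod, unname(eb$t[, cmp]), tolerance = 1e-6)
    expect_equal(res$p_raw, unname(eb$p.value[, cmp]), tolerance = 1e-6)
  }
})

test_that("de_fit methods are coherent", {
  sim <- simulate_dataset(simulation_config(n_genes = 80, seed = 4))
  fit <- de_fit(sim$expression)
  expect_s3_class(fit, "de_fit")
  expect_equal(dim(coef(fit)), c(80L, 4L))
  expect_equal(fitted(fit) + residuals(fit), sim$expression$values)
  # residuals are orthogonal to the cell-means design: they sum to ~0 per cell
  r <- residuals(fit)
  key <- flightDE:::group_keys(sim$expression$meta)
  for (cl in levels(key))
    expect_equal(max(abs(rowSums(r[, key == cl, drop = FALSE]))), 0,
                 tolerance = 1e-10)
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_length(reps, 2L)
  expect_equal(dim(reps[[1]]), dim(sim$expression))
  expect_output(print(fit), "prior df")
  expect_output(print(summary(fit)), "posterior variance")
})
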