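#' Per-gene cell-means fits for the 2x2 design
#'
#' Computes, for every gene, the four group means (one per
#' genotype-by-environment cell) and the residual variance pooled across all
#' four cells, with residual degrees of freedom N - 4 shared by all genes.
#'
#' @param x an [expression_set()] on the log2 scale with at least two
#'   samples in each of the four cells.
#' @return A list with elements `gene_ids`, `means` (genes x 4 matrix, cell
#'   order `WT.ground`, `WT.flight`, `KO.ground`, `KO.flight`), `n` (per-cell
#'   sample counts), `s2` (pooled residual variances) and `df` (residual
#'   degrees of freedom).
#' @export
fit_gene_models <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "log2")
    stop("model fitting expects log2-scale values", call. = FALSE)
  key <- group_keys(x$meta)
  n <- table(key)
  if (any(n < 2L))
    stop("every genotype x environment cell needs >= 2 samples; short: ",
         paste(names(n)[n < 2L], collapse = ", "), call. = FALSE)
  cells <- levels(key)
  v <- x$values
  means <- matrix(NA_real_, nrow(v), length(cells),
                  dimnames = list(rownames(v), cells))
  rss <- numeric(nrow(v))
  for (cl in cells) {
    yc <- v[, key == cl, drop = FALSE]
    m <- rowMeans(yc)
    means[, cl] <- m
    rss <- rss + rowSums((yc - m)^2)
  }
  df <- ncol(v) - length(cells)
  list(gene_ids = rownames(v), means = means,
       n = stats::setNames(as.integer(n), cells),
       s2 = rss / df, df = df)
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0),
# with a bisection fallback if the iteration leaves the domain.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (iter in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (!is.finite(x) || x <= 0) { x <- NA_real_; break }
      if (-dif / x < 1e-8) return(x)
    }
    # bisection fallback: trigamma is strictly decreasing on (0, Inf)
    lo <- 1e-8; hi <- 1e8
    for (iter in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > yy) lo <- mid else hi <- mid
      if (hi / lo - 1 < 1e-10) break
    }
    sqrt(lo * hi)
  }, numeric(1L))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior (d0, s0^2) for gene-wise
#' variances by moment-matching the marginal distribution of log s_g^2 (a
#' scaled-F model): the excess of the observed variance of log s_g^2 over
#' the sampling floor trigamma(df/2) determines d0 through the trigamma
#' function, and the mean determines s0^2 through the digamma function. When
#' the observed dispersion does not exceed the floor, d0 is infinite and
#' every posterior variance equals s0^2. Estimated d0 above 1e6 is reported
#' as infinite.
#'
#' @param s2 per-gene residual variances (zeros are excluded from prior
#'   estimation but still receive a posterior value).
#' @param df residual degrees of freedom (single value, shared by genes).
#' @return A list with `prior_df` (d0), `prior_var` (s0^2) and `var_post`
#'   (posterior variances `(d0 s0^2 + df s^2) / (d0 + df)`).
#' @export
estimate_moderation <- function(s2, df) {
  if (df < 1) stop("residual df must be >= 1", call. = FALSE)
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    stop("need >= 2 genes with positive residual variance", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e6) d0 <- Inf
  } else {
    d0 <- Inf
  }
  # with infinite d0 the gene variances carry no excess dispersion and the
  # prior is simply their average; otherwise invert the digamma-based mean
  s02 <- if (is.infinite(d0)) mean(s2[ok])
         else exp(emean + digamma(d0 / 2) - log(d0 / 2))
  var_post <- squeeze_variances(s2, df, d0, s02)
  list(prior_df = d0, prior_var = s02, var_post = var_post)
}

squeeze_variances <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) rep(s02, length(s2))
  else if (d0 == 0) s2
  else (d0 * s02 + df * s2) / (d0 + df)
}

#' Fit the moderated factorial differential-expression model
#'
#' The single entry point of the modelling pipeline: per-gene cell-means
#' least squares ([fit_gene_models()]) followed by empirical-Bayes variance
#' moderation ([estimate_moderation()]). The returned object feeds
#' [contrast_test()] and the usual methods (`print`, `summary`, `coef`,
#' `fitted`, `residuals`, `simulate`, `plot`).
#'
#' @param x an [expression_set()] on the log2 scale with >= 2 samples per
#'   genotype-by-environment cell.
#' @param prior_df optional override of the prior degrees of freedom d0:
#'   `NULL` (default) estimates it from the data, `0` disables moderation
#'   (ordinary pooled t-tests), `Inf` shrinks every variance fully to the
#'   prior mean.
#' @return An object of class `"de_fit"`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 200, seed = 3))
#' fit <- de_fit(sim$expression)
#' fit
#' @export
de_fit <- function(x, prior_df = NULL) {
  fits <- fit_gene_models(x)
  if (is.null(prior_df)) {
    mod <- estimate_moderation(fits$s2, fits$df)
  } else {
    if (prior_df < 0) stop("'prior_df' must be >= 0", call. = FALSE)
    s02 <- if (prior_df == 0) mean(fits$s2)
           else estimate_moderation(fits$s2, fits$df)$prior_var
    mod <- list(prior_df = prior_df, prior_var = s02,
                var_post = squeeze_variances(fits$s2, fits$df, prior_df, s02))
  }
  structure(c(fits,
              list(prior_df = mod$prior_df, prior_var = mod$prior_var,
                   s2_post = mod$var_post,
                   df_total = fits$df + mod$prior_df,
                   data = x)),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("de_fit: %d genes, %d samples (cells: %s)\n",
              length(x$gene_ids), sum(x$n),
              paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", ")))
  cat(sprintf("residual df: %d; prior df (d0): %s; prior variance (s0^2): %.5g\n",
              x$df, format(x$prior_df, digits = 4), x$prior_var))
  invisible(x)
}

#' @export
summary.de_fit <- function(object, ...) {
  out <- list(n_genes = length(object$gene_ids), n = object$n,
              df = object$df, prior_df = object$prior_df,
              prior_var = object$prior_var,
              s2_quartiles = stats::quantile(object$s2, c(.25, .5, .75)),
              s2_post_quartiles = stats::quantile(object$s2_post,
                                                  c(.25, .5, .75)))
  class(out) <- "summary.de_fit"
  out
}

#' @export
print.summary.de_fit <- function(x, ...) {
  cat(sprintf("Moderated factorial DE fit: %d genes\n", x$n_genes))
  cat("samples per cell:",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  cat(sprintf("residual df %d + prior df %s\n", x$df,
              format(x$prior_df, digits = 4)))
  cat(sprintf("prior variance s0^2 = %.5g\n", x$prior_var))
  cat("residual variance quartiles:",
      paste(signif(x$s2_quartiles, 4), collapse = " / "), "\n")
  cat("posterior variance quartiles:",
      paste(signif(x$s2_post_quartiles, 4), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.de_fit <- function(object, ...) object$means

#' @export
fitted.de_fit <- function(object, ...) {
  key <- as.character(group_keys(object$data$meta))
  f <- object$means[, key, drop = FALSE]
  colnames(f) <- colnames(object$data$values)
  f
}

#' @export
residuals.de_fit <- function(object, ...) {
  object$data$values - fitted(object)
}

#' Simulate replicate datasets from a fitted model
#'
#' Parametric simulation: new log2 matrices are drawn as fitted cell means
#' plus Gaussian noise with each gene's posterior variance.
#'
#' @param object a [de_fit()].
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [expression_set()] objects.
#' @export
simulate.de_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    noise <- matrix(stats::rnorm(length(f)), nrow(f)) * sqrt(object$s2_post)
    expression_set(f + noise, object$data$meta, scale = "log2")
  })
}

#' Variance-shrinkage plot for a moderated fit
#'
#' Plots per-gene residual standard deviations against their posterior
#' (moderated) values, with the prior standard deviation s0 marked; genes
#' line up on the identity when d0 = 0 and collapse onto s0 as d0 grows.
#'
#' @param x a [de_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.de_fit <- function(x, ...) {
  graphics::plot(sqrt(x$s2), sqrt(x$s2_post),
                 xlab = "residual SD", ylab = "posterior SD",
                 pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = sqrt(x$prior_var), col = 2)
  invisible(x)
}
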