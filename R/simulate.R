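#' Category labels of the cross-contrast taxonomy
#'
#' The classification assigns each gene one primary label according to its
#' significance pattern across the four canonical comparisons; see
#' [classify_gene()] for the defining criteria. The first seven labels are
#' plantable by the simulator.
#'
#' @return Character vector of the nine category labels.
#' @export
de_categories <- function() {
  c("shared_same", "shared_opposite", "required", "corrected",
    "genotype_dependent", "compensated", "persistent_genotype_difference",
    "other_pattern", "none")
}

plantable_categories <- function() de_categories()[1:7]

#' Simulation settings for a 2x2 genotype-by-environment experiment
#'
#' Describes a synthetic microarray-like experiment: log2-scale intensities
#' for `n_genes` genes over four sample groups (WT/KO crossed with
#' ground/flight) with unbalanced replication, gene-wise variances drawn from
#' a scaled inverse-chi-square prior, and planted effects arranged so that
#' each requested classification category has known ground-truth members.
#'
#' @param n_genes number of genes.
#' @param replicates named integer vector of per-cell replicate counts with
#'   names `WT.ground`, `WT.flight`, `KO.ground`, `KO.flight`; every count
#'   must be at least 2. Defaults to 5 wild-type and 3 knockout plates per
#'   environment.
#' @param baseline_mean,baseline_sd mean and spread (log2 units) of the
#'   per-gene baseline intensity.
#' @param effect_size magnitude (log2 units) of planted effects.
#' @param prior_df prior degrees of freedom d0 of the scaled
#'   inverse-chi-square variance prior; `Inf` fixes every gene's variance at
#'   `prior_var`.
#' @param prior_var prior variance s0^2 (squared log2 units).
#' @param category_counts named integer vector mapping category labels (see
#'   [de_categories()], first seven entries) to numbers of genes planted with
#'   that pattern; unnamed categories default to 0 and remaining genes are
#'   null.
#' @param knockout_effect optional log2 deficit (e.g. `-7.27`) planted as a
#'   pure genotype effect in both environments for one designated gene
#'   (`"KO_MARKER"`), emulating the transcript knocked out by a T-DNA
#'   insertion; used by [verify_knockout()].
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              replicates = c(WT.ground = 5L, WT.flight = 5L,
                                             KO.ground = 3L, KO.flight = 3L),
                              baseline_mean = 8, baseline_sd = 1.5,
                              effect_size = 4,
                              prior_df = 4, prior_var = 0.05,
                              category_counts = NULL,
                              knockout_effect = NULL,
                              seed = 1L) {
  cells <- c("WT.ground", "WT.flight", "KO.ground", "KO.flight")
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("invalid 'n_genes': must be a positive count", call. = FALSE)
  if (is.null(names(replicates)) || !setequal(names(replicates), cells))
    stop("invalid 'replicates': needs names ", paste(cells, collapse = ", "),
         call. = FALSE)
  replicates <- replicates[cells]
  if (any(replicates < 2))
    stop("invalid 'replicates': every cell needs >= 2 samples", call. = FALSE)
  if (!is.numeric(baseline_sd) || baseline_sd < 0)
    stop("invalid 'baseline_sd': must be >= 0", call. = FALSE)
  if (!is.numeric(prior_df) || length(prior_df) != 1L || prior_df <= 0)
    stop("invalid 'prior_df': must be > 0 (possibly Inf)", call. = FALSE)
  if (!is.numeric(prior_var) || length(prior_var) != 1L || prior_var <= 0)
    stop("invalid 'prior_var': must be > 0", call. = FALSE)
  cc <- stats::setNames(integer(7L), plantable_categories())
  if (!is.null(category_counts)) {
    bad <- setdiff(names(category_counts), plantable_categories())
    if (length(bad))
      stop("invalid 'category_counts': unknown category ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(category_counts < 0))
      stop("invalid 'category_counts': negative count", call. = FALSE)
    cc[names(category_counts)] <- as.integer(category_counts)
  }
  n_planted <- sum(cc) + as.integer(!is.null(knockout_effect))
  if (n_planted > n_genes)
    stop("invalid 'category_counts': planted genes (", n_planted,
         ") exceed n_genes (", n_genes, ")", call. = FALSE)
  if (!is.null(knockout_effect) &&
      (!is.numeric(knockout_effect) || length(knockout_effect) != 1L))
    stop("invalid 'knockout_effect': must be a single log2 value",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 replicates = as.integer(replicates) |>
                   stats::setNames(cells),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_size = effect_size,
                 prior_df = prior_df, prior_var = prior_var,
                 category_counts = cc,
                 knockout_effect = knockout_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Planted-effect pattern for a classification category
#'
#' Maps a category label to the effect tuple that, in expectation (no
#' noise), produces exactly that category's significance pattern across the
#' four comparisons. Effects are parameterized as the ground genotype effect
#' (KO minus WT on the ground) and the two within-genotype environment
#' effects (flight minus ground); the flight genotype effect is their
#' deterministic consequence.
#'
#' @param category one of the first seven labels of [de_categories()], or
#'   `"null"`.
#' @param effect_size effect magnitude in log2 units.
#' @return Named numeric vector with elements `genotype_effect`,
#'   `environment_effect_WT`, `environment_effect_KO` and
#'   `flight_genotype_effect`.
#' @examples
#' category_effect_pattern("corrected", 4)
#' @export
category_effect_pattern <- function(category, effect_size) {
  e <- effect_size
  eff <- switch(category,
    shared_same        = c(0,  e,  e),
    shared_opposite    = c(0,  e, -e),
    required           = c(e,  e,  0),
    corrected          = c(-e, 0,  e),
    genotype_dependent = c(0,  e,  0),
    compensated        = c(0,  0,  e),
    persistent_genotype_difference = c(-e, 0, 0),
    null               = c(0, 0, 0),
    stop("unknown category: '", category, "'", call. = FALSE))
  names(eff) <- c("genotype_effect", "environment_effect_WT",
                  "environment_effect_KO")
  c(eff, flight_genotype_effect =
      unname(eff[1L] + eff[3L] - eff[2L]))
}

# expected log2 mean of each cell given a baseline and an effect tuple
cell_means_from_effects <- function(baseline, eff) {
  c(WT.ground = baseline,
    WT.flight = baseline + eff[["environment_effect_WT"]],
    KO.ground = baseline + eff[["genotype_effect"]],
    KO.flight = baseline + eff[["genotype_effect"]] +
      eff[["environment_effect_KO"]])
}

#' Simulate a factorial expression dataset with known ground truth
#'
#' Draws a per-gene baseline, plants the effect pattern of each requested
#' category ([category_effect_pattern()]), draws gene-wise variances from the
#' scaled inverse-chi-square prior s0^2 * d0 / chi^2(d0) (fixed at s0^2 when
#' d0 is infinite), and adds Gaussian noise on the log2 scale with a single
#' shared variance per gene across all four groups.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `expression` (an [expression_set()], log2
#'   scale) and `truth` (data.frame: `gene_id`, the four planted effects,
#'   `true_variance`, `intended_category`).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 100, seed = 7))
#' table(sim$truth$intended_category)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(config$seed)
  ng <- config$n_genes
  reps <- config$replicates
  cells <- names(reps)

  cat_vec <- rep("null", ng)
  i <- 1L
  for (cat in plantable_categories()) {
    k <- config$category_counts[[cat]]
    if (k > 0L) {
      cat_vec[i:(i + k - 1L)] <- cat
      i <- i + k
    }
  }
  ko_idx <- NA_integer_
  if (!is.null(config$knockout_effect)) {
    ko_idx <- i
    cat_vec[ko_idx] <- "persistent_genotype_difference"
  }

  gene_id <- sprintf("gene_%05d", seq_len(ng))
  if (!is.na(ko_idx)) gene_id[ko_idx] <- "KO_MARKER"

  eff <- t(vapply(cat_vec, category_effect_pattern,
                  numeric(4L), effect_size = config$effect_size))
  rownames(eff) <- NULL
  if (!is.na(ko_idx)) {
    ke <- config$knockout_effect
    eff[ko_idx, ] <- c(ke, 0, 0, ke)
  }

  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  true_var <- if (is.infinite(config$prior_df)) {
    rep(config$prior_var, ng)
  } else {
    config$prior_var * config$prior_df / stats::rchisq(ng, config$prior_df)
  }

  sample_id <- unlist(lapply(cells, function(cl) {
    short <- c(WT.ground = "GWt", WT.flight = "FWt",
               KO.ground = "GHsf", KO.flight = "FHsf")[[cl]]
    paste0(short, "_", seq_len(reps[[cl]]))
  }))
  cell_of_sample <- rep(cells, reps)
  meta <- data.frame(
    sample_id = sample_id,
    genotype = sub("\\..*$", "", cell_of_sample),
    environment = sub("^.*\\.", "", cell_of_sample))

  mu_cells <- cbind(
    WT.ground = baseline,
    WT.flight = baseline + eff[, "environment_effect_WT"],
    KO.ground = baseline + eff[, "genotype_effect"],
    KO.flight = baseline + eff[, "genotype_effect"] +
      eff[, "environment_effect_KO"])
  mu <- mu_cells[, cell_of_sample, drop = FALSE]
  noise <- matrix(stats::rnorm(ng * length(sample_id)), ng) * sqrt(true_var)
  values <- mu + noise
  dimnames(values) <- list(gene_id, sample_id)

  truth <- data.frame(gene_id = gene_id, eff,
                      true_variance = true_var,
                      intended_category = cat_vec)
  list(expression = expression_set(values, meta, scale = "log2"),
       truth = truth)
}

#' Write a simulated dataset to tab-delimited files
#'
#' Writes the expression matrix and sample metadata in the layout read back
#' by [read_expression_matrix()], plus the ground-truth table.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_set(sim$expression, paths[["expression"]],
                       paths[["meta"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
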