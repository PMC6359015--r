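#' Run the full comparative-transcriptomics pipeline
#'
#' Reads an expression matrix and sample metadata, optionally filters
#' undetected genes, log-transforms and quantile-normalizes, fits the
#' moderated factorial model, tests the four canonical comparisons, calls
#' differential expression, classifies every gene by its cross-contrast
#' pattern, and (optionally) runs term enrichment per comparison. All
#' tabular artifacts are written as TSV under `out_dir`; progress is logged
#' to standard error.
#'
#' @param expr_path,meta_path input expression and metadata TSVs (layout of
#'   [read_expression_matrix()]).
#' @param out_dir output directory, created if needed.
#' @param calls_path optional detection-call TSV; genes absent in every
#'   sample are removed.
#' @param annotation_path optional GMT-style annotation; when given, the
#'   significant genes of each comparison are tested for term
#'   over-representation against the post-filter gene universe.
#' @param thresholds a [threshold_config()].
#' @param scale scale of the stored intensities (`"log2"` or `"raw"`).
#' @param log2 log2-transform after filtering (required when `scale` is
#'   `"raw"` and the default in that case).
#' @param quantile apply quantile normalization.
#' @param intensity_floor optional raw-scale detection floor used when no
#'   calls are available.
#' @param min_mapped,alpha enrichment settings (see [fisher_enrichment()]).
#' @param verbose log progress to standard error.
#' @return Invisibly, a list with the fitted model (`fit`), the per-
#'   comparison results (`contrasts`), the classification (`categories`),
#'   and the written file paths (`files`).
#' @export
run_pipeline <- function(expr_path, meta_path, out_dir,
                         calls_path = NULL, annotation_path = NULL,
                         thresholds = threshold_config(),
                         scale = c("log2", "raw"),
                         log2 = identical(match.arg(scale), "raw"),
                         quantile = FALSE,
                         intensity_floor = NULL,
                         min_mapped = 5L, alpha = 0.05,
                         verbose = TRUE) {
  scale <- match.arg(scale)
  say <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), "[pipeline] ", ...)
  for (p in c(expr_path, meta_path, calls_path, annotation_path))
    if (!file.exists(p))
      stop("[ingest] input file not found: ", p, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say("reading ", expr_path)
  x <- read_expression_matrix(expr_path, meta_path, calls_path, scale = scale)
  n0 <- nrow(x$values)
  x <- filter_absent(x, intensity_floor = intensity_floor)
  say("detection filter: ", n0 - nrow(x$values), " of ", n0, " genes removed")
  if (log2) x <- log2_transform(x)
  if (quantile) {
    say("quantile normalization")
    x <- quantile_normalize(x)
  }

  say("fitting moderated factorial model (", nrow(x$values), " genes)")
  fit <- de_fit(x)
  say(sprintf("prior df d0 = %s, prior variance s0^2 = %.4g",
              format(fit$prior_df, digits = 4), fit$prior_var))

  files <- character(0L)
  contrasts <- list()
  for (cmp in de_comparisons()) {
    res <- call_de(contrast_test(fit, cmp), thresholds)
    contrasts[[cmp]] <- res
    f <- file.path(out_dir, paste0("de_", cmp, ".tsv"))
    write_contrast(res, f)
    files[paste0("de_", cmp)] <- f
    say(cmp, ": ", sum(res$status == "up"), " up, ",
        sum(res$status == "down"), " down")
  }

  categories <- classify_all(build_comparison_groups(contrasts))
  fcat <- file.path(out_dir, "categories.tsv")
  fsum <- file.path(out_dir, "summary.tsv")
  write_categories(categories, fcat, fsum)
  files["categories"] <- fcat
  files["summary"] <- fsum

  if (!is.null(annotation_path)) {
    ann <- read_annotation(annotation_path)
    universe <- categories$gene_id
    for (cmp in de_comparisons()) {
      hits <- contrasts[[cmp]]$gene_id[contrasts[[cmp]]$status != "ns"]
      if (!length(hits)) next
      enr <- fisher_enrichment(hits, universe, ann,
                               min_mapped = min_mapped, alpha = alpha)
      f <- file.path(out_dir, paste0("enrichment_", cmp, ".tsv"))
      utils::write.table(as.data.frame(enr), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[paste0("enrichment_", cmp)] <- f
      say("enrichment ", cmp, ": ", sum(enr$significant), " of ",
          nrow(enr), " terms significant")
    }
  }
  say("done; artifacts in ", out_dir)
  invisible(list(fit = fit, contrasts = contrasts, categories = categories,
                 files = files))
}

#' Verify a knockout by its ground-state genotype contrast
#'
#' Reports the raw-scale group-mean intensities of one gene per genotype on
#' the ground, its knockout-vs-wild-type ground contrast (log2 fold change
#' and p-value), and whether the gene is significantly depressed in the
#' knockout — the standard sanity check that a T-DNA insertion actually
#' silenced its target.
#'
#' @param x an [expression_set()] (log2 scale).
#' @param gene_id the target gene.
#' @param thresholds a [threshold_config()].
#' @return A one-row data.frame: `gene_id`, `mean_WT_ground`,
#'   `mean_KO_ground` (raw-intensity scale), `log2FC`, `p_raw`, `p_adj`,
#'   `depressed` (logical).
#' @export
verify_knockout <- function(x, gene_id, thresholds = threshold_config()) {
  stopifnot(inherits(x, "expr_set"))
  if (!gene_id %in% rownames(x$values))
    stop("gene '", gene_id, "' not present", call. = FALSE)
  fit <- de_fit(x)
  res <- call_de(contrast_test(fit, "GHsf_vs_GWt"), thresholds)
  row <- res[res$gene_id == gene_id, ]
  means <- fit$means[gene_id, ]
  out <- data.frame(gene_id = gene_id,
                    mean_WT_ground = 2^means[["WT.ground"]],
                    mean_KO_ground = 2^means[["KO.ground"]],
                    log2FC = row$log2FC, p_raw = row$p_raw,
                    p_adj = row$p_adj,
                    depressed = row$status == "down")
  rownames(out) <- NULL
  out
}
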