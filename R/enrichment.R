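#' Read a GMT-style term annotation file
#'
#' One term per line: term id, tab, description, tab, then tab-separated
#' gene identifiers.
#'
#' @param path path to the annotation file.
#' @return A list of class `"annotation_map"` with elements `genes` (named
#'   list of gene-id vectors) and `description` (named character vector).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short))
    stop("annotation line(s) with fewer than 3 fields: line ",
         paste(utils::head(which(short), 5L), collapse = ", "), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicated term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- ids
  structure(list(genes = genes,
                 description = stats::setNames(
                   vapply(fields, `[[`, character(1L), 2L), ids)),
            class = "annotation_map")
}

#' One-sided Fisher (hypergeometric) term over-representation
#'
#' Singular enrichment analysis: for each term, counts hits in the gene list
#' (k) and in the background (K) and computes the upper-tail hypergeometric
#' probability of at least k hits when drawing n = length(gene_list) genes
#' from the N background genes. Terms mapping fewer than `min_mapped`
#' background genes are excluded. No multiplicity adjustment is applied by
#' default, matching the SEA "NOT-adjust" convention; `adjust = TRUE` adds a
#' BH column and gates significance on it.
#'
#' @param gene_list character vector of genes of interest (must be contained
#'   in `background`).
#' @param background character vector: the gene universe (typically all
#'   detected genes).
#' @param annotation an [read_annotation()] map, or a named list of gene-id
#'   vectors.
#' @param min_mapped minimum number of background genes a term must map to
#'   (default 5).
#' @param alpha significance level (default 0.05).
#' @param adjust apply BH adjustment before gating significance.
#' @return A data.frame of class `"enrichment_result"`, one row per retained
#'   term, ordered by p: `term_id`, `description`, `k`, `K`, `n`, `N`, `p`
#'   (plus `p_adj` when `adjust`), `significant`.
#' @export
fisher_enrichment <- function(gene_list, background, annotation,
                              min_mapped = 5L, alpha = 0.05,
                              adjust = FALSE) {
  if (min_mapped < 1L) stop("'min_mapped' must be >= 1", call. = FALSE)
  background <- unique(as.character(background))
  gene_list <- unique(as.character(gene_list))
  stray <- setdiff(gene_list, background)
  if (length(stray))
    stop("gene list not contained in background: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  if (inherits(annotation, "annotation_map")) {
    term_genes <- annotation$genes
    descr <- annotation$description
  } else {
    term_genes <- annotation
    descr <- stats::setNames(rep("", length(annotation)), names(annotation))
  }
  N <- length(background)
  n <- length(gene_list)
  K <- vapply(term_genes, function(g) length(intersect(g, background)),
              integer(1L))
  keep <- K >= min_mapped
  term_genes <- term_genes[keep]
  K <- K[keep]
  k <- vapply(term_genes, function(g) length(intersect(g, gene_list)),
              integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = names(term_genes),
                    description = unname(descr[names(term_genes)]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p))
  if (adjust) {
    res$p_adj <- bh_adjust(res$p)
    res$significant <- res$p_adj < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
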