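#' Assemble per-gene status patterns across the four comparisons
#'
#' @param calls a named list with one element per comparison in
#'   [de_comparisons()]; each element is either a [call_de()] result or a
#'   character vector of statuses named by gene. All four must cover the
#'   same gene universe.
#' @return A data.frame of class `"comparison_groups"`: `gene_id`, one status
#'   column per comparison, and (when available from the inputs) one
#'   `lfc_<comparison>` column per comparison.
#' @export
build_comparison_groups <- function(calls) {
  comps <- de_comparisons()
  if (!is.list(calls) || !setequal(names(calls), comps))
    stop("'calls' must be a named list covering exactly: ",
         paste(comps, collapse = ", "), call. = FALSE)
  as_status <- function(x) {
    if (inherits(x, "de_contrast")) {
      if (is.null(x$status))
        stop("contrast lacks a 'status' column; run call_de() first",
             call. = FALSE)
      list(status = stats::setNames(x$status, x$gene_id),
           lfc = stats::setNames(x$log2FC, x$gene_id))
    } else {
      if (is.null(names(x)))
        stop("status vectors must be named by gene", call. = FALSE)
      list(status = x, lfc = NULL)
    }
  }
  parts <- lapply(calls[comps], as_status)
  universe <- names(parts[[1L]]$status)
  for (cmp in comps) {
    st <- parts[[cmp]]$status
    bad <- setdiff(st, c("up", "down", "ns"))
    if (length(bad))
      stop("invalid status token(s) in ", cmp, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    miss <- setdiff(universe, names(st))
    extra <- setdiff(names(st), universe)
    if (length(miss) || length(extra))
      stop("gene universe mismatch in ", cmp, ": ",
           paste(utils::head(c(miss, extra), 5L), collapse = ", "),
           call. = FALSE)
  }
  out <- data.frame(gene_id = universe)
  for (cmp in comps) out[[cmp]] <- unname(parts[[cmp]]$status[universe])
  if (!any(vapply(parts, function(p) is.null(p$lfc), logical(1L))))
    for (cmp in comps)
      out[[paste0("lfc_", cmp)]] <- unname(parts[[cmp]]$lfc[universe])
  rownames(out) <- NULL
  class(out) <- c("comparison_groups", "data.frame")
  out
}

#' Classify a cross-comparison status pattern
#'
#' Assigns the primary category for a 4-tuple of statuses over the
#' comparisons (in order) `FWt_vs_GWt`, `FHsf_vs_GHsf`, `GHsf_vs_GWt`,
#' `FHsf_vs_FWt`:
#'
#' * `shared_same` / `shared_opposite` — both vertical (flight vs ground)
#'   comparisons significant, with equal / opposite signs;
#' * `required` — significant in the WT vertical and the ground horizontal
#'   comparison, non-significant in the KO vertical and flight horizontal:
#'   the wild type must move its expression to a level the knockout already
#'   has;
#' * `corrected` — significant in the KO vertical and the ground horizontal,
#'   non-significant in the WT vertical and flight horizontal: the knockout
#'   must move to the wild-type level to reach the flight-adapted state;
#' * `genotype_dependent` — significant only in the WT vertical and the
#'   flight horizontal;
#' * `compensated` — significant only in the KO vertical and the flight
#'   horizontal;
#' * `persistent_genotype_difference` — both horizontal comparisons
#'   significant with equal sign;
#' * `other_pattern` — any other pattern with at least one significant
#'   status; `none` — all non-significant.
#'
#' Precedence (shared > required/corrected > genotype-dependent/compensated >
#' persistent > other) makes the assignment total and deterministic; apart
#' from the shared/persistent overlap the criteria are already mutually
#' exclusive. No sign constraint is imposed within required/corrected —
#' member genes may move in either direction.
#'
#' @param pattern a character vector of 4 statuses (`"up"`, `"down"`,
#'   `"ns"`), or an n-by-4 matrix/data.frame of them.
#' @return A character vector of category labels (length 1 for a 4-vector).
#' @examples
#' classify_gene(c("up", "ns", "down", "ns"))  # required
#' @export
classify_gene <- function(pattern) {
  if (is.data.frame(pattern)) pattern <- as.matrix(pattern)
  if (!is.matrix(pattern)) {
    if (length(pattern) != 4L)
      stop("a single pattern must have 4 statuses", call. = FALSE)
    pattern <- matrix(pattern, nrow = 1L)
  }
  if (ncol(pattern) != 4L)
    stop("pattern matrix must have 4 columns", call. = FALSE)
  bad <- setdiff(unique(as.vector(pattern)), c("up", "down", "ns"))
  if (length(bad))
    stop("invalid status token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  fwt  <- pattern[, 1L]  # FWt_vs_GWt   (WT vertical)
  fhsf <- pattern[, 2L]  # FHsf_vs_GHsf (KO vertical)
  ggg  <- pattern[, 3L]  # GHsf_vs_GWt  (ground horizontal)
  fff  <- pattern[, 4L]  # FHsf_vs_FWt  (flight horizontal)
  sig <- function(s) s != "ns"
  out <- rep("none", nrow(pattern))
  any_sig <- sig(fwt) | sig(fhsf) | sig(ggg) | sig(fff)
  out[any_sig] <- "other_pattern"
  out[sig(ggg) & sig(fff) & ggg == fff] <- "persistent_genotype_difference"
  out[sig(fwt) & !sig(fhsf) & !sig(ggg) & sig(fff)] <- "genotype_dependent"
  out[!sig(fwt) & sig(fhsf) & !sig(ggg) & sig(fff)] <- "compensated"
  out[sig(fwt) & !sig(fhsf) & sig(ggg) & !sig(fff)] <- "required"
  out[!sig(fwt) & sig(fhsf) & sig(ggg) & !sig(fff)] <- "corrected"
  out[sig(fwt) & sig(fhsf) & fwt == fhsf] <- "shared_same"
  out[sig(fwt) & sig(fhsf) & fwt != fhsf] <- "shared_opposite"
  out
}

#' Classify every gene and tally the categories
#'
#' @param groups a [build_comparison_groups()] result.
#' @return A data.frame of class `"category_assignment"`: the input columns
#'   plus `primary_category`. Attributes `category_counts` (named table) and
#'   `comparison_counts` (data.frame with significant/up/down per
#'   comparison) carry the tallies; see `summary()`.
#' @export
classify_all <- function(groups) {
  stopifnot(inherits(groups, "comparison_groups"))
  comps <- de_comparisons()
  pat <- as.matrix(as.data.frame(groups)[, comps])
  groups$primary_category <- classify_gene(pat)
  cat_counts <- table(factor(groups$primary_category,
                             levels = de_categories()))
  comp_counts <- data.frame(
    comparison = comps,
    up = vapply(comps, function(cm) sum(groups[[cm]] == "up"), integer(1L)),
    down = vapply(comps, function(cm) sum(groups[[cm]] == "down"),
                  integer(1L)))
  comp_counts$significant <- comp_counts$up + comp_counts$down
  rownames(comp_counts) <- NULL
  attr(groups, "category_counts") <- cat_counts
  attr(groups, "comparison_counts") <- comp_counts
  class(groups) <- c("category_assignment", "data.frame")
  groups
}

#' @export
summary.category_assignment <- function(object, ...) {
  out <- list(comparison_counts = attr(object, "comparison_counts"),
              category_counts = attr(object, "category_counts"))
  class(out) <- "summary.category_assignment"
  out
}

#' @export
print.summary.category_assignment <- function(x, ...) {
  cat("Differentially expressed genes per comparison:\n")
  print(x$comparison_counts)
  cat("\nGenes per category:\n")
  print(x$category_counts)
  invisible(x)
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("category_assignment: %d genes\n", nrow(x)))
  print(summary(x))
  invisible(x)
}

#' Write the per-gene category table and the count summary
#'
#' @param assignment a [classify_all()] result.
#' @param path output TSV path for the per-gene table.
#' @param summary_path optional output TSV path for the per-comparison and
#'   per-category counts.
#' @return `assignment`, invisibly.
#' @export
write_categories <- function(assignment, path, summary_path = NULL) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    cc <- attr(assignment, "comparison_counts")
    kc <- attr(assignment, "category_counts")
    long <- rbind(
      data.frame(group = cc$comparison, metric = "up", count = cc$up),
      data.frame(group = cc$comparison, metric = "down", count = cc$down),
      data.frame(group = cc$comparison, metric = "significant",
                 count = cc$significant),
      data.frame(group = names(kc), metric = "category",
                 count = as.integer(kc)))
    utils::write.table(long, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(assignment)
}

#' Log2 fold-change heat map of categorized genes
#'
#' Plain image of the four per-comparison log2 fold changes for all genes
#' assigned to any named category (rows grouped by category, no clustering),
#' standing in for publication heat-map figures.
#'
#' @param x a [classify_all()] result that carries `lfc_*` columns.
#' @param ... passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
plot.category_assignment <- function(x, ...) {
  lfc_cols <- paste0("lfc_", de_comparisons())
  if (!all(lfc_cols %in% names(x)))
    stop("no log2FC columns available; build groups from call_de() results",
         call. = FALSE)
  named <- setdiff(de_categories(), c("other_pattern", "none"))
  keep <- x$primary_category %in% named
  if (!any(keep)) stop("no genes in a named category", call. = FALSE)
  sub <- x[keep, , drop = FALSE]
  sub <- sub[order(factor(sub$primary_category, levels = named)), ]
  m <- as.matrix(sub[, lfc_cols])
  rownames(m) <- sub$gene_id
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = de_comparisons(),
                 las = 2, cex.axis = 0.7)
  invisible(m)
}
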