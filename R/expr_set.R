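#' Construct an expression set
#'
#' Bundles a gene-by-sample intensity matrix with per-sample factor labels
#' (genotype: WT or KO; environment: ground or flight), a scale flag, and
#' optional Affymetrix-style detection calls. This is the container consumed
#' by every downstream step ([filter_absent()], [log2_transform()],
#' [quantile_normalize()], [de_fit()]).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). No missing values are allowed.
#' @param meta data.frame with columns `sample_id`, `genotype` (`"WT"` or
#'   `"KO"`) and `environment` (`"ground"` or `"flight"`), one row per
#'   column of `values`.
#' @param scale `"log2"` for already log-transformed intensities or `"raw"`
#'   for linear-scale intensities.
#' @param calls optional character matrix of detection calls (`"P"`, `"M"`,
#'   `"A"`) with the same dimensions and dimnames as `values`.
#' @return An object of class `"expr_set"`: a list with elements `values`,
#'   `meta`, `scale` and `calls`.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    genotype = c("WT", "WT", "KO", "KO"),
#'                    environment = c("ground", "flight", "ground", "flight"))
#' x <- expression_set(m, meta)
#' dim(x)
#' @export
expression_set <- function(values, meta, scale = c("log2", "raw"),
                           calls = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyDuplicated(gid))
    stop("gene identifiers (rownames) must be present and unique; duplicated: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (is.null(sid) || anyDuplicated(sid))
    stop("sample identifiers (colnames) must be present and unique",
         call. = FALSE)
  if (anyNA(values)) {
    w <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gid[w[1L]], sid[w[2L]]), call. = FALSE)
  }
  meta <- as.data.frame(meta)
  need <- c("sample_id", "genotype", "environment")
  if (!all(need %in% names(meta)))
    stop("'meta' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  missing_meta <- setdiff(sid, meta$sample_id)
  if (length(missing_meta))
    stop("metadata missing sample(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  extra_meta <- setdiff(meta$sample_id, sid)
  if (length(extra_meta))
    stop("metadata lists sample(s) absent from the matrix: ",
         paste(extra_meta, collapse = ", "), call. = FALSE)
  meta <- meta[match(sid, meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  meta$genotype <- as.character(meta$genotype)
  meta$environment <- as.character(meta$environment)
  bad_g <- setdiff(unique(meta$genotype), c("WT", "KO"))
  if (length(bad_g))
    stop("genotype must be 'WT' or 'KO'; found: ",
         paste(bad_g, collapse = ", "), call. = FALSE)
  bad_e <- setdiff(unique(meta$environment), c("ground", "flight"))
  if (length(bad_e))
    stop("environment must be 'ground' or 'flight'; found: ",
         paste(bad_e, collapse = ", "), call. = FALSE)
  if (!is.null(calls)) {
    if (!is.matrix(calls) || !identical(dim(calls), dim(values)))
      stop("'calls' must be a matrix with the same shape as 'values'",
           call. = FALSE)
    if (!identical(dimnames(calls), dimnames(values)))
      stop("'calls' dimnames must match 'values'", call. = FALSE)
    bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
    if (length(bad))
      stop("detection calls must be 'P', 'M' or 'A'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, meta = meta, scale = scale, calls = calls),
            class = "expr_set")
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$calls)) "" else ", with detection calls"))
  tab <- table(genotype = x$meta$genotype, environment = x$meta$environment)
  print(tab)
  invisible(x)
}

#' @export
`[.expr_set` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  calls <- if (is.null(x$calls)) NULL else x$calls[i, j, drop = FALSE]
  meta <- x$meta[match(colnames(v), x$meta$sample_id), , drop = FALSE]
  expression_set(v, meta, scale = x$scale, calls = calls)
}

# "genotype.environment" key per sample, in a fixed cell order
group_keys <- function(meta) {
  factor(paste(meta$genotype, meta$environment, sep = "."),
         levels = c("WT.ground", "WT.flight", "KO.ground", "KO.flight"))
}

#' Read an expression matrix and its sample metadata
#'
#' Reads a tab-delimited expression table (header row of sample identifiers,
#' first column of gene identifiers) together with a sample metadata table
#' (`sample_id`, `genotype`, `environment`), validating the join. Sample and
#' gene order are preserved from the expression file.
#'
#' @param path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @param calls_path optional path to a detection-call TSV with the same
#'   layout as the expression table.
#' @param scale scale of the stored intensities, `"log2"` (default) or
#'   `"raw"`.
#' @return An [expression_set()].
#' @seealso [write_expression_set()] for the inverse operation.
#' @export
read_expression_matrix <- function(path, meta_path, calls_path = NULL,
                                   scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression file '", path, "' needs a gene-id column plus >= 1 sample",
         call. = FALSE)
  gid <- tab[[1L]]
  if (anyDuplicated(gid)) {
    d <- unique(gid[duplicated(gid)])
    stop("duplicate gene id(s) in '", path, "': ",
         paste(utils::head(d, 5L), collapse = ", "), call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L,
                                     dimnames = list(NULL, names(tab)[-1L]))
  if (anyNA(num)) {
    w <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric or missing value in '%s' at gene '%s' (line %d), sample '%s'",
      path, gid[w[1L]], w[1L] + 1L, colnames(num)[w[2L]]), call. = FALSE)
  }
  rownames(num) <- gid
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            colClasses = "character")
  calls <- NULL
  if (!is.null(calls_path)) {
    ctab <- utils::read.delim(calls_path, check.names = FALSE,
                              colClasses = "character")
    calls <- as.matrix(ctab[-1L])
    rownames(calls) <- ctab[[1L]]
    if (!identical(dimnames(calls), dimnames(num)))
      stop("detection-call file '", calls_path,
           "' does not match the expression table layout", call. = FALSE)
  }
  expression_set(num, meta, scale = scale, calls = calls)
}

#' Write an expression set to tab-delimited files
#'
#' @param x an [expression_set()].
#' @param path output path for the expression TSV (first column `gene_id`).
#' @param meta_path output path for the metadata TSV.
#' @param calls_path optional output path for the detection-call TSV.
#' @return `x`, invisibly.
#' @export
write_expression_set <- function(x, path, meta_path, calls_path = NULL) {
  stopifnot(inherits(x, "expr_set"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(calls_path)) {
    if (is.null(x$calls)) stop("no detection calls to write", call. = FALSE)
    ctab <- data.frame(gene_id = rownames(x$calls), x$calls,
                       check.names = FALSE)
    utils::write.table(ctab, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Remove undetected genes
#'
#' When detection calls are available, drops genes whose call is absent
#' (`"A"`) in every sample. Without calls, drops genes whose maximum
#' raw-scale intensity falls below `intensity_floor`; with neither calls nor
#' a floor the matrix is returned unchanged. Surviving genes keep their order
#' and values.
#'
#' @param x an [expression_set()].
#' @param calls optional detection-call matrix overriding `x$calls`.
#' @param intensity_floor optional positive raw-scale intensity threshold
#'   used only when no calls are available; genes with maximum raw intensity
#'   strictly below it are removed.
#' @return The filtered [expression_set()].
#' @export
filter_absent <- function(x, calls = x$calls, intensity_floor = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (!is.null(calls)) {
    if (!identical(dim(calls), dim(x$values)))
      stop("'calls' shape does not match the expression matrix", call. = FALSE)
    keep <- rowSums(calls != "A") > 0L
  } else if (!is.null(intensity_floor)) {
    if (!is.numeric(intensity_floor) || length(intensity_floor) != 1L ||
        intensity_floor <= 0)
      stop("'intensity_floor' must be a single positive value", call. = FALSE)
    mx <- apply(x$values, 1L, max)
    if (x$scale == "log2") mx <- 2^mx
    keep <- mx >= intensity_floor
  } else {
    return(x)
  }
  x[keep, seq_len(ncol(x$values))]
}

#' Log2-transform raw intensities
#'
#' @param x an [expression_set()] on the raw scale with strictly positive
#'   values.
#' @return The same set with `values = log2(values)` and `scale = "log2"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "raw")
    stop("matrix is already on the log2 scale", call. = FALSE)
  if (any(x$values <= 0)) {
    w <- which(x$values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive intensity at gene '%s', sample '%s'",
                 rownames(x$values)[w[1L]], colnames(x$values)[w[2L]]),
         call. = FALSE)
  }
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every column onto the common reference distribution obtained by
#' averaging the column-wise sorted values, preserving within-column rank
#' order. Ties within a column receive the mean of the reference quantiles
#' they span (midrank convention).
#'
#' @param x an [expression_set()] on the log2 scale with at least two
#'   samples.
#' @return The normalized [expression_set()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "log2")
    stop("quantile normalization expects log2-scale values", call. = FALSE)
  v <- x$values
  if (ncol(v) < 2L)
    stop("quantile normalization is undefined for a single sample",
         call. = FALSE)
  target <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    o <- order(v[, j])
    sorted <- v[o, j]
    grp <- cumsum(c(TRUE, diff(sorted) != 0))
    gm <- tapply(target, grp, mean)
    out[o, j] <- gm[grp]
  }
  x$values <- out
  x
}
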