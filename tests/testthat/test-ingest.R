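toy_set <- function(values = matrix(2^(1:12), 3, 4), scale = "raw",
                    calls = NULL) {
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("s", seq_len(ncol(values))))
  if (!is.null(calls)) dimnames(calls) <- dimnames(values)
  meta <- data.frame(sample_id = colnames(values),
                     genotype = rep(c("WT", "KO"), each = 2),
                     environment = rep(c("ground", "flight"), 2))
  expression_set(values, meta, scale = scale, calls = calls)
}

test_that("expression files round-trip and metadata is validated", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "e.tsv"); mp <- file.path(dir, "m.tsv")

  x <- toy_set(matrix(round(rnorm(12, 8), 6), 3, 4), scale = "log2")
  write_expression_set(x, ep, mp)
  y <- read_expression_matrix(ep, mp)
  expect_equal(y$values, x$values)
  expect_equal(y$meta, x$meta)
  expect_equal(dim(y), c(3L, 4L))

  # simulator output round-trips bit-identically
  sim <- simulate_dataset(simulation_config(n_genes = 25, seed = 5))
  paths <- write_simulation(sim, file.path(dir, "sim"))
  back <- read_expression_matrix(paths[["expression"]], paths[["meta"]])
  back2 <- read_expression_matrix(paths[["expression"]], paths[["meta"]])
  expect_identical(back$values, back2$values)
  expect_equal(back$values, sim$expression$values, tolerance = 1e-12)
  expect_identical(back$meta, sim$expression$meta)

  # metadata missing one sample -> error naming it
  meta <- utils::read.delim(mp)
  utils::write.table(meta[-2L, ], mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression_matrix(ep, mp), "s2")

  # duplicate gene ids and non-numeric cells are rejected with context
  tab <- utils::read.delim(ep, check.names = FALSE)
  tab$gene_id <- c("g1", "g1", "g3")
  utils::write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(ep, file.path(dir, "sim/samples.tsv")),
               "duplicate gene id")
  tab$gene_id <- c("g1", "g2", "g3")
  tab[2, 3] <- "oops"
  utils::write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(ep, mp), "g2")
})

test_that("detection-call and intensity-floor filtering follow the rules", {
  calls <- matrix("P", 4, 4)
  calls[2, ] <- "A"                       # absent everywhere -> removed
  calls[3, ] <- c("A", "A", "P", "A")     # one present call -> retained
  x <- toy_set(matrix(2^(1:16), 4, 4), calls = calls)
  f <- filter_absent(x)
  expect_identical(rownames(f$values), c("g1", "g3", "g4"))
  expect_identical(f$values, x$values[c(1, 3, 4), ])

  # all-present calls leave the matrix unchanged
  allp <- toy_set(matrix(2^(1:16), 4, 4), calls = matrix("P", 4, 4))
  expect_identical(filter_absent(allp)$values, allp$values)

  # no calls: max raw intensity below the floor -> removed, at floor -> kept
  vals <- matrix(c(10, 20, 49,
                   10, 20, 30,
                   50, 20, 30,
                   10, 49, 30), 3, 4)
  y <- toy_set(vals)
  kept <- filter_absent(y, intensity_floor = 50)
  expect_identical(rownames(kept$values), "g1")
  expect_error(filter_absent(y, intensity_floor = 0), "positive")
  expect_error(filter_absent(y, intensity_floor = -1), "positive")

  # no calls and no floor: nothing filtered
  expect_identical(filter_absent(y)$values, y$values)
})

test_that("log2 transform is exact, located, and invertible", {
  x <- toy_set(matrix(c(1024, rep(1, 11)), 3, 4))
  lx <- log2_transform(x)
  expect_identical(lx$scale, "log2")
  expect_equal(lx$values[1, 1], 10)
  expect_equal(lx$values[2, 1], 0)
  expect_error(log2_transform(lx), "already")

  # round-trip: log2(2^z) recovers z to machine precision
  set.seed(1)
  z <- matrix(rnorm(12), 3, 4)
  rt <- log2_transform(toy_set(2^z))
  expect_equal(unname(rt$values), z, tolerance = 1e-14)

  bad <- toy_set(matrix(c(-1, 2^(2:12)), 3, 4))
  expect_error(log2_transform(bad), "gene 'g1', sample 's1'")
})

test_that("quantile normalization matches the rank-mean oracle", {
  # hand-computed 2x2 example: columns [1,3] and [2,6] -> both [1.5, 4.5]
  x <- expression_set(matrix(c(1, 3, 2, 6), 2, 2,
                             dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                      data.frame(sample_id = c("s1", "s2"),
                                 genotype = c("WT", "KO"),
                                 environment = c("ground", "ground")),
                      scale = "log2")
  qn <- quantile_normalize(x)
  expect_equal(unname(qn$values),
               matrix(c(1.5, 4.5, 1.5, 4.5), 2, 2))

  # rank order preserved even when input ranks differ across columns
  y <- expression_set(matrix(c(3, 1, 2, 4, 6, 5), 3, 2,
                             dimnames = list(paste0("g", 1:3),
                                             c("s1", "s2"))),
                      data.frame(sample_id = c("s1", "s2"),
                                 genotype = c("WT", "KO"),
                                 environment = c("ground", "ground")),
                      scale = "log2")
  qy <- quantile_normalize(y)
  expect_identical(apply(qy$values, 2, rank), apply(y$values, 2, rank))

  # identical columns are unchanged
  z <- toy_set(matrix(rep(c(5, 1, 3), 4), 3, 4), scale = "log2")
  expect_equal(quantile_normalize(z)$values, z$values)

  # sorted columns identical to machine precision; permutation symmetry
  set.seed(42)
  w <- toy_set(matrix(rnorm(48, 8), 12, 4), scale = "log2")
  qw <- quantile_normalize(w)
  srt <- apply(qw$values, 2, sort)
  expect_true(max(abs(srt - srt[, 1])) < 1e-12)
  perm <- c(3, 1, 4, 2)
  qp <- quantile_normalize(w[1:12, perm])
  expect_equal(qp$values, qw$values[, perm])

  # ties take the mean of the spanned quantiles (midrank convention)
  tied <- expression_set(matrix(c(1, 1, 1, 5, 1, 2, 3, 4), 4, 2,
                                dimnames = list(paste0("g", 1:4),
                                                c("s1", "s2"))),
                         data.frame(sample_id = c("s1", "s2"),
                                    genotype = "WT",
                                    environment = "ground"),
                         scale = "log2")
  qt <- quantile_normalize(tied)
  target <- rowMeans(apply(tied$values, 2, sort))
  expect_equal(unname(qt$values[1:3, 1]), rep(mean(target[1:3]), 3))
  expect_equal(unname(qt$values[4, 1]), unname(target[4]))

  single <- w[1:12, 1]
  expect_error(quantile_normalize(single), "single sample")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(7)
  v <- matrix(rnorm(200, 8, 2), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  x <- expression_set(v, data.frame(sample_id = paste0("s", 1:4),
                                    genotype = rep(c("WT", "KO"), 2),
                                    environment = rep(c("ground", "flight"),
                                                      each = 2)),
                      scale = "log2")
  expect_equal(quantile_normalize(x)$values,
               limma::normalizeQuantiles(v), tolerance = 1e-12)
})
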