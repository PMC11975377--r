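test_that("cell metrics match a brute-force summation oracle", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2), x = c(5, 5, 3),
                            dims = c(3, 2),
                            dimnames = list(paste0("c", 1:3),
                                            c("mt-a", "b")))
  met <- compute_cell_metrics(m, mito_genes = "mt-a")
  expect_equal(met$library_size, c(10, 3, 0))
  expect_equal(met$n_genes, c(2, 1, 0))
  expect_equal(met$mito_frac, c(0.5, 0, 0))   # all-zero cell: 0 by convention

  sim <- qc_sim()
  met <- compute_cell_metrics(sim$counts)
  dense <- as.matrix(sim$counts)
  mito <- grep("^mt-", colnames(dense))
  expect_equal(met$library_size, unname(rowSums(dense)))
  expect_equal(met$n_genes, unname(rowSums(dense > 0)))
  expect_equal(met$mito_frac,
               unname(rowSums(dense[, mito]) / pmax(rowSums(dense), 1)))
})

test_that("hard thresholds are strict at the published boundaries", {
  met <- data.frame(cell = paste0("c", 1:4),
                    library_size = c(1000, 1001, 5000, 5000),
                    n_genes = c(800, 800, 2000, 2000),
                    mito_frac = c(0.05, 0.05, 0.20, 0.199))
  met$complexity_keep <- TRUE
  kept <- threshold_filter(met)
  expect_false("c1" %in% kept)   # library exactly 1000 removed (strict >)
  expect_true("c2" %in% kept)
  expect_false("c3" %in% kept)   # mito exactly 20% removed (strict <)
  expect_true("c4" %in% kept)
})

test_that("complexity residuals match the closed-form OLS oracle", {
  set.seed(1)
  lib <- 10^runif(60, 3, 4.5)
  ngene <- 10^(0.6 * log10(lib) + 0.5 + rnorm(60, 0, 0.05))
  met <- data.frame(cell = seq_len(60), library_size = lib, n_genes = ngene,
                    mito_frac = 0)
  fitd <- fit_complexity_model(met)
  x <- log10(lib); y <- log10(ngene)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fitd$residual, as.numeric(y - X %*% beta), tolerance = 1e-10)

  # cells exactly on a line: all kept
  met2 <- data.frame(cell = 1:20, library_size = 10^seq(3, 4, length = 20),
                     n_genes = 10^(0.5 * seq(3, 4, length = 20)),
                     mito_frac = 0)
  expect_true(all(fit_complexity_model(met2)$complexity_keep))

  # one cell 10x below the predicted complexity: residual -1, removed
  met3 <- met2
  met3$n_genes[10] <- met3$n_genes[10] / 10
  f3 <- fit_complexity_model(met3)
  expect_lt(f3$residual[10], -0.5)
  expect_false(f3$complexity_keep[10])
})

test_that("KDE split finds the antimode of a clear mixture", {
  set.seed(2)
  lx <- c(rnorm(500, 3.0, 0.1), rnorm(500, 4.5, 0.1))
  met <- data.frame(library_size = 10^lx)
  sp <- split_bimodal_library(met)
  expect_gt(sp$antimode, 3.3)
  expect_lt(sp$antimode, 4.2)
  truth <- rep(c("low", "high"), each = 500)
  expect_gt(mean(sp$mode == truth), 0.99)

  # permutation invariance
  perm <- sample(nrow(met))
  sp2 <- split_bimodal_library(met[perm, , drop = FALSE])
  expect_identical(sp2$mode, sp$mode[perm])

  # unimodal fallback
  met3 <- data.frame(library_size = 10^rnorm(500, 4, 0.15))
  sp3 <- split_bimodal_library(met3)
  expect_true(all(sp3$mode == "high"))
})

test_that("cluster reassignment recovers injected low-quality cells", {
  sim <- qc_sim()
  met <- compute_cell_metrics(sim$counts)
  sp <- split_bimodal_library(met)
  norm <- normalize_median_log1p(sim$counts)
  re <- cluster_quality_reassignment(norm$values, met, sp$mode)
  low_truth <- sim$truth$cells$quality == "low"
  expect_gt(mean(re$quality[low_truth] == "low"), 0.95)
  # labels are per-cluster constant
  expect_true(all(tapply(re$quality, re$clusters,
                         function(q) length(unique(q))) == 1))
})

test_that("full QC cascade recovers truth quality labels", {
  sim <- qc_sim()
  qc <- qc_filter(sim$counts)
  truth_high <- sim$truth$cells$cell[sim$truth$cells$quality == "high"]
  truth_low <- sim$truth$cells$cell[sim$truth$cells$quality == "low"]
  removed <- setdiff(sim$truth$cells$cell, qc$kept)
  expect_gt(mean(truth_low %in% removed), 0.95)      # sensitivity
  expect_lt(mean(truth_high %in% removed), 0.02)     # false removals
  # idempotence: re-filtering the kept set removes nothing
  qc2 <- qc_filter(sim$counts[qc$kept, , drop = FALSE])
  expect_identical(sort(qc2$kept), sort(qc$kept))
})

test_that("downsampling conserves targets and hypergeometric proportions", {
  sim <- simulate_tissue(sim_config(n_cells = 10, n_genes = 200, seed = 6))
  ds <- downsample_counts(sim$counts, target = 1000, seed = 1)
  lib0 <- Matrix::rowSums(sim$counts)
  lib1 <- Matrix::rowSums(ds)
  expect_true(all(lib1[lib0 > 1000] == 1000))
  expect_true(all(lib1[lib0 <= 1000] == lib0[lib0 <= 1000]))
  expect_true(all(as.matrix(ds) <= as.matrix(sim$counts)))
  # no-op at target >= max library
  ds2 <- downsample_counts(sim$counts, target = max(lib0), seed = 1)
  expect_identical(as.matrix(ds2), as.matrix(sim$counts))

  # mean proportions match the hypergeometric oracle over repeated draws
  cell <- matrix(as.numeric(sim$counts[1, ]), 1,
                 dimnames = list("c1", colnames(sim$counts)))
  tot <- sum(cell)
  reps <- sapply(1:1000, function(s)
    as.matrix(downsample_counts(Matrix::Matrix(cell, sparse = TRUE),
                                target = 500, seed = s))[1, ])
  exp_mean <- 500 * cell[1, ] / tot
  exp_var <- 500 * (cell[1, ] / tot) * (1 - cell[1, ] / tot) *
    (tot - 500) / (tot - 1)
  se <- sqrt(exp_var / 1000)
  ok <- abs(rowMeans(reps) - exp_mean) <= 3 * pmax(se, 1e-12)
  expect_gt(mean(ok), 0.98)
})

test_that("rank-sum DEG machinery matches exhaustive ranks and is calibrated", {
  # brute-force rank computation on a 10-cell toy
  xa <- c(0, 1, 3, 7, 2); xb <- c(5, 8, 9, 1, 4)
  mat <- matrix(c(xa, xb), ncol = 1)
  res <- cnpaxes:::rank_sum_by_gene(mat, c(rep(TRUE, 5), rep(FALSE, 5)))
  r <- rank(c(xa, xb))
  expect_equal(res$statistic, sum(r[1:5]) - 5 * 6 / 2)
  expect_equal(res$p,
               wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)

  # identical groups: p roughly uniform, few FDR discoveries
  set.seed(3)
  null_mat <- matrix(rpois(200 * 400, 2), 200, 400)
  colnames(null_mat) <- paste0("g", 1:400)
  res <- rank_sum_quality_degs(null_mat[1:100, ], null_mat[101:200, ])
  expect_lt(mean(res$fdr < 0.05), 0.05)

  # gene expressed only in the low group ranks among the smallest p
  lowonly <- null_mat
  lowonly[1:100, 7] <- 0
  lowonly[101:200, 7] <- rpois(100, 5)
  res2 <- rank_sum_quality_degs(lowonly[1:100, ], lowonly[101:200, ])
  expect_lte(rank(res2$p)[7], 3)

  # all-tied gene gives p = 1
  tied <- matrix(1, 20, 1)
  expect_equal(cnpaxes:::rank_sum_by_gene(tied, rep(c(TRUE, FALSE), 10))$p, 1)
})
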