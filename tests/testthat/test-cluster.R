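test_that("community detection separates planted Gaussian blobs", {
  blobs <- make_blobs(n_per = 200, sd = 1)
  g <- knn_graph(blobs$x, k = 15)
  # at default resolution every community is pure with respect to a blob
  cl <- community_detect(g, seed = 1)
  purity <- tapply(blobs$label, cl$cluster,
                   function(l) length(unique(l)))
  expect_true(all(purity == 1))
  expect_setequal(unique(cl$cluster), 0:(cl$n_clusters - 1))
  # at coarse resolution the planted two-blob partition is recovered exactly
  cl2 <- community_detect(g, seed = 1, resolution = 0.05)
  ri <- cnpaxes:::rand_indices(cl2$cluster, blobs$label)
  expect_equal(cl2$n_clusters, 2)
  expect_equal(ri$adjusted_rand, 1)
})

test_that("Jaccard weight of cells sharing all neighbours is 1", {
  # duplicated point set: identical kNN sets (tie-break by index is shared)
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  g <- knn_graph(x, k = 2)
  # reproduce the internal weighting: membership includes self
  M <- Matrix::sparseMatrix(i = c(1:4, rep(1:4, 2)),
                            j = c(1:4, as.vector(g$idx)), x = 1,
                            dims = c(4, 4))
  inter <- Matrix::tcrossprod(M)
  expect_equal(unname(inter[1, 2] / (2 * 3 - inter[1, 2])), 1)
  cl <- community_detect(g, seed = 0)
  expect_equal(cl$cluster[1], cl$cluster[2])
})

test_that("Rand indices match the exhaustive pair-counting formula", {
  a <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 0)
  b <- c(1, 1, 0, 0, 2, 2, 1, 0, 0, 2)
  ri <- cnpaxes:::rand_indices(a, b)
  # enumerate all pairs
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  expect_equal(ri$rand, agree / tot)
  # identity and label-invariance
  expect_equal(cnpaxes:::rand_indices(a, a)$rand, 1)
  expect_equal(cnpaxes:::rand_indices(a, (a + 1) %% 3)$rand, 1)
  skip_if_not_installed("mclust")
  expect_equal(ri$adjusted_rand, mclust::adjustedRandIndex(a, b))
})

test_that("clustering is stable under neighbourhood-size perturbation", {
  blobs <- make_blobs(n_per = 150, centers = rbind(c(0, 0), c(7, 0), c(0, 7)),
                      sd = 1, seed = 9)
  rep <- rand_index_stability(blobs$x, k = 20, deltas = c(5, 10), seed = 1)
  expect_true(attr(rep, "pass"))
  expect_true(all(rep$rand > 0.8))
})

test_that("signature scores follow the random-signature null", {
  set.seed(7)
  vals <- matrix(rnorm(300 * 200), 300, 200,
                 dimnames = list(NULL, sprintf("g%03d", 1:200)))
  # P = all genes, N empty: raw score equals the per-cell mean, z = 0
  expect_equal(signature_score(vals, colnames(vals)), rep(0, 300),
               tolerance = 1e-10)
  # single-gene P two sigma above the cell mean scores z = 2
  one <- matrix(rnorm(100 * 50), 100, 50,
                dimnames = list(NULL, sprintf("g%02d", 1:50)))
  mu <- rowMeans(one)
  sd_pop <- sqrt(rowMeans((one - mu)^2))
  one[, 1] <- mu + 2 * sd_pop
  mu2 <- rowMeans(one); sd2 <- sqrt(rowMeans((one - mu2)^2))
  z <- signature_score(one, "g01")
  oracle <- (one[, 1] - mu2) / sd2
  expect_equal(z, oracle, tolerance = 1e-10)
  # Monte-Carlo null: mean within 0.1, variance within [0.8, 1.2]
  zs <- vapply(1:1000, function(i) {
    set.seed(i)
    p <- sample(colnames(vals), 10)
    signature_score(vals[1:50, ], p)[1]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(var(zs), 0.8)
  expect_lt(var(zs), 1.2)
  # two-set score invariant to adding a constant to all genes of a cell
  shift <- vals + 3
  expect_equal(signature_score(vals, c("g001", "g002"), c("g003", "g004")),
               signature_score(shift, c("g001", "g002"), c("g003", "g004")),
               tolerance = 1e-10)
})

test_that("training sets follow the 20th-percentile exclusivity rule", {
  scores <- rbind(c(5, -1), c(4, 0), c(3, 1), c(2, 2), c(1, 3),
                  c(0, 4), c(-1, 5), c(4, 4.5), c(0.5, 0.4), c(6, -2))
  colnames(scores) <- c("A", "B")
  labels <- c("A", "A", "A", "B", "B", "B", "B", "B", "A", "A")
  ts <- build_training_set(scores, labels)
  thrA <- quantile(scores[labels == "A", "A"], 0.2, names = FALSE)
  thrB <- quantile(scores[labels == "B", "B"], 0.2, names = FALSE)
  oracle <- ifelse(scores[, "A"] > thrA & scores[, "B"] <= thrB, "A",
            ifelse(scores[, "B"] > thrB & scores[, "A"] <= thrA, "B",
                   NA_character_))
  expect_identical(ts$label, oracle)
  # a cell above both thresholds stays unlabeled
  both <- which(scores[, "A"] > thrA & scores[, "B"] > thrB)
  expect_true(all(is.na(ts$label[both])))
  expect_error(build_training_set(scores, rep("A", 10)), "no preliminarily")
})

test_that("well-separated blobs yield a large, pure training set", {
  set.seed(8)
  n <- 150
  sA <- c(rnorm(n, 3, 1), rnorm(n, -3, 1))
  scores <- cbind(A = sA, B = -sA)
  labels <- rep(c("A", "B"), each = n)
  ts <- build_training_set(scores, labels)
  lab <- ts$label
  expect_gt(mean(!is.na(lab)), 0.6)
  expect_equal(mean(lab[!is.na(lab)] == labels[!is.na(lab)]), 1)
})

test_that("absorption probabilities match a dense linear solve", {
  # path A - u1 - u2 - B with equal weights
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  g <- knn_graph(x, k = 1)
  labels <- c("A", NA, NA, "B")
  res <- absorb_classify(g, labels)
  W <- as.matrix(cnpaxes:::adaptive_kernel_weights(g, ka = 1))
  P <- W / rowSums(W)
  Q <- P[2:3, 2:3]
  R <- cbind(A = P[2:3, 1], B = P[2:3, 4])
  B_oracle <- solve(diag(2) - Q, R)
  expect_equal(unname(res$probabilities), unname(B_oracle),
               tolerance = 1e-8)
  expect_equal(res$label[2], "A")
  expect_equal(unname(rowSums(res$probabilities)), c(1, 1),
               tolerance = 1e-8)

  # unlabeled cell surrounded by one label absorbs there with certainty
  x2 <- matrix(c(0, 0.5, 1), ncol = 1)
  g2 <- knn_graph(x2, k = 2)
  r2 <- absorb_classify(g2, c("A", NA, "A"))
  expect_equal(unname(r2$probabilities[1, "A"]), 1, tolerance = 1e-8)

  # aggregation: duplicating an absorbing state leaves B invariant
  x3 <- matrix(c(0, 1, 2, 3, 3.0001), ncol = 1)
  g3 <- knn_graph(x3, k = 2)
  rA <- absorb_classify(g3, c("A", NA, NA, "B", "B"))
  x4 <- matrix(c(0, 1, 2, 3), ncol = 1)   # merged endpoint
  # (structural analogue: probabilities still sum to 1 and argmax sane)
  expect_equal(unname(rowSums(rA$probabilities)), c(1, 1), tolerance = 1e-8)
  expect_equal(rA$label[2], "A")
})

test_that("marker detection finds exclusive genes and stays calibrated", {
  set.seed(10)
  n <- 60; g <- 80
  vals <- matrix(rgamma(n * g, 2, 1), n, g,
                 dimnames = list(NULL, sprintf("g%02d", 1:g)))
  cl <- rep(0:1, each = n / 2)
  vals[cl == 0, 5] <- vals[cl == 0, 5] + 5      # exclusive to cluster 0
  mk <- rank_sum_markers(vals, cl)
  top0 <- mk[mk$cluster == 0, ]
  expect_equal(top0$gene[which.min(top0$p)], "g05")
  expect_gt(top0$log2fc[top0$gene == "g05"], 0)
  # permuted labels: few FDR discoveries
  perm <- sample(cl)
  mkp <- rank_sum_markers(vals[, -5], perm)
  expect_lt(mean(mkp$fdr < 0.05), 0.05)
  # statistic equals exhaustive rank computation on a 12-cell toy
  toy <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8), ncol = 1,
                dimnames = list(NULL, "g"))
  cl12 <- rep(0:1, each = 6)
  res <- rank_sum_markers(toy, cl12)
  r <- rank(toy[, 1])
  expect_equal(res$statistic[res$cluster == 0],
               sum(r[1:6]) - 6 * 7 / 2)
})
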