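# Genes generated from latent block factors: within-block correlation
# ~rho, across-block ~0.
make_block_genes <- function(n_cells = 300, per_block = 12, blocks = 3,
                             rho = 0.9, seed = 1) {
  set.seed(seed)
  noise_sd <- sqrt(1 / rho - 1)
  vals <- NULL; lab <- NULL
  for (b in seq_len(blocks)) {
    f <- rnorm(n_cells)
    block <- sapply(seq_len(per_block), function(i)
      f + rnorm(n_cells, 0, noise_sd))
    vals <- cbind(vals, block)
    lab <- c(lab, rep(b, per_block))
  }
  colnames(vals) <- sprintf("g%03d", seq_len(ncol(vals)))
  list(vals = vals, label = lab)
}

# Brute-force Ward agglomeration (Lance-Williams on squared distances,
# heights reported on the distance scale as in hclust ward.D2).
ward_oracle_heights <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  repeat {
    if (length(active) == 1) break
    sub <- d2[active, active]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, sqrt(d2[i, j]))
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

test_that("Ward linkage heights match an exhaustive agglomeration oracle", {
  set.seed(2)
  vals <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(NULL, paste0("g", 1:8)))
  dend <- correlation_linkage(vals, colnames(vals))
  oracle <- ward_oracle_heights(dist(cor(vals)))
  expect_equal(sort(dend$hclust$height), sort(oracle), tolerance = 1e-10)
  # two perfectly correlated genes merge first at the minimum height
  vals2 <- vals
  vals2[, 2] <- 2 * vals2[, 1] + 3
  dend2 <- correlation_linkage(vals2, colnames(vals2))
  first <- dend2$hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))
  # constant gene excluded with a warning
  vals3 <- vals; vals3[, 5] <- 1
  expect_warning(correlation_linkage(vals3, colnames(vals3)), "constant")
})

test_that("knee point maximizes chord distance with normalization", {
  # exhaustive chord-distance scan oracle
  x <- 1:5; y <- c(10, 5, 1, 0.9, 0.8)
  xn <- (x - min(x)) / diff(range(x)); yn <- (y - min(y)) / diff(range(y))
  d <- abs((xn[5] - xn[1]) * (yn[1] - yn) - (yn[5] - yn[1]) * (xn[1] - xn))
  expect_equal(knee_point(x, y), which.max(d))
  expect_equal(knee_point(x, y), 3)
  # straight line: degenerate, first interior point with warning
  expect_warning(ki <- knee_point(1:5, 2 * (1:5) + 1), "straight")
  expect_equal(ki, 2L)
  # invariant to affine rescaling of either coordinate
  expect_equal(knee_point(10 * x + 3, y), 3)
  expect_equal(knee_point(x, -2 * y + 7), 3)
  expect_error(knee_point(1:2, 1:2), "at least 3")
})

test_that("knee-point cut recovers planted correlation blocks exactly", {
  bg <- make_block_genes()
  dend <- correlation_linkage(bg$vals, colnames(bg$vals))
  cut <- select_cut(dend)
  expect_equal(cut$n_clusters, 3)
  ri <- cnpaxes:::rand_indices(cut$assignment, bg$label)
  expect_equal(ri$adjusted_rand, 1)
  # achieved within-cluster correlation on strong blocks is high
  expect_gte(cut$achieved_correlation, 0.5)
  # three-cluster cut separates blocks exactly
  cl3 <- cutree(dend$hclust, k = 3)
  expect_equal(cnpaxes:::rand_indices(cl3, bg$label)$adjusted_rand, 1)
})

test_that("fixed-height cuts are nested and ordered by size", {
  bg <- make_block_genes(per_block = 8, blocks = 4, seed = 3)
  dend <- correlation_linkage(bg$vals, colnames(bg$vals))
  hmax <- max(dend$hclust$height)
  expect_equal(length(unique(cut_modules(dend, 0))), ncol(bg$vals))
  expect_equal(length(unique(cut_modules(dend, hmax + 1))), 1)
  coarse <- cut_modules(dend, 0.8 * hmax)
  mid <- cut_modules(dend, 0.5 * hmax)
  fine <- cut_modules(dend, 0.3 * hmax)
  # nestedness: every finer cluster sits inside exactly one coarser cluster
  for (pair in list(list(fine, mid), list(mid, coarse))) {
    f <- pair[[1]]; c <- pair[[2]]
    expect_true(all(tapply(c, f, function(v) length(unique(v))) == 1))
  }
  # ids ordered by decreasing size
  sizes <- as.numeric(table(coarse)[as.character(sort(unique(coarse)))])
  expect_true(all(diff(sizes) <= 0))
})

test_that("module scores track the planted mediolateral pattern", {
  sim <- default_sim()
  sp <- late_spatial()
  # module score formula oracle: one-set signature score
  genes <- colnames(sp$norm)[1:20]
  expect_equal(module_score(sp$norm, genes),
               signature_score(sp$norm, genes), tolerance = 1e-12)
  # all genes: z = 0 everywhere
  expect_equal(module_score(sp$norm, colnames(sp$norm)),
               rep(0, nrow(sp$norm)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # the planted midline-gradient module tracks truth |ml|
  ml_genes <- sim$truth$genes$gene[sim$truth$genes$archetype ==
                                     "ml_gradient_down"]
  sc <- module_score(sp$norm, ml_genes)
  expect_gte(abs(cor(sc, abs(sp$truth$ml), method = "spearman")), 0.8)
})

test_that("multi-resolution cuts resolve two-dimensional archetypes", {
  sim <- default_sim()
  sp <- late_spatial()
  tg <- sim$truth$genes
  spatial <- tg$gene[tg$archetype %in%
                       c("ap_step", "ml_gradient_up", "ml_gradient_down",
                         "two_dim")]
  dend <- correlation_linkage(sp$norm, spatial)
  cut <- select_cut(dend)
  # the knee lands at a biologically sized module count
  expect_gte(cut$n_clusters, 5)
  expect_lte(cut$n_clusters, 30)
  mid <- cut_modules(dend, 0.6 * cut$D_star)
  # the intermediate cut resolves the planted 2D (AP-window x ML) classes
  genes_2d <- tg[tg$archetype == "two_dim", ]
  lab2 <- vapply(genes_2d$param, function(p) paste0(p$ap, p$ml),
                 character(1))
  ri <- cnpaxes:::rand_indices(mid[genes_2d$gene], lab2)
  expect_gte(ri$adjusted_rand, 0.8)
  # and separates AP-restricted midline genes (per AP window) from the
  # pan-AP midline gradient genes
  down2d <- genes_2d[vapply(genes_2d$param, function(p) p$ml == "down",
                            logical(1)), ]
  restricted_lab <- paste0("window", vapply(down2d$param,
                                            function(p) p$ap, numeric(1)))
  pan <- tg$gene[tg$archetype == "ml_gradient_down"]
  both <- c(down2d$gene, pan)
  truth_split <- c(restricted_lab, rep("pan", length(pan)))
  ri2 <- cnpaxes:::rand_indices(mid[both], truth_split)
  expect_gte(ri2$adjusted_rand, 0.8)
  # nestedness across the three stringencies
  coarse <- cut_modules(dend, cut$D_star)
  fine <- cut_modules(dend, 0.4 * cut$D_star)
  for (pair in list(list(fine, mid), list(mid, coarse))) {
    expect_true(all(tapply(pair[[2]], pair[[1]],
                           function(v) length(unique(v))) == 1))
  }
})
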