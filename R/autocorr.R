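#' Symmetric neighbour weights on a latent space
#'
#' Adaptive Gaussian kernel on the kNN graph of the latent space, with
#' each cell's outgoing weights normalized to sum 1, then symmetrized by
#' arithmetic mean; the diagonal is zero.
#'
#' @param latent cells x dims matrix or embedding list (a single diffusion
#'   component may be passed as a one-column matrix).
#' @param k nearest neighbours (default 30).
#' @param ka adaptive bandwidth neighbour (default `floor(k/3)`).
#' @return sparse symmetric weight matrix.
#' @export
neighbor_weights <- function(latent, k = 30, ka = max(1L, floor(k / 3))) {
  x <- if (is.list(latent)) latent$values else as_dense(latent)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  graph <- knn_graph(x, k)
  A <- adaptive_affinity(graph, ka)
  A <- Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
  W <- (A + Matrix::t(A)) / 2
  Matrix::diag(W) <- 0
  methods::as(W, "CsparseMatrix")
}

#' Graph-weighted local autocorrelation of one gene
#'
#' Standardizes the gene across cells to mean 0 and (population) variance
#' 1, then computes the weighted pairwise-product statistic
#' \eqn{H = \sum_{i<j} w_{ij} x_i x_j}. Under the independence null
#' \eqn{E[H] = 0} and \eqn{Var[H] = \sum_{i<j} w_{ij}^2}, giving
#' \eqn{Z = H / \sqrt{Var[H]}} and the one-sided normal p-value
#' (positive local similarity is the signal).
#'
#' @param weights symmetric zero-diagonal weight matrix from
#'   [neighbor_weights()].
#' @param x per-cell expression values of one gene.
#' @return list `H`, `Z`, `p` (zero-variance genes give `H = Z = 0`,
#'   `p = 1`).
#' @export
local_autocorrelation <- function(weights, x) {
  v <- stats::var(x) * (length(x) - 1) / length(x)
  if (v == 0) return(list(H = 0, Z = 0, p = 1))
  z <- (x - mean(x)) / sqrt(v)
  H <- as.numeric(Matrix::crossprod(z, weights %*% z)) / 2
  varH <- sum(weights@x^2) / 2
  Z <- H / sqrt(varH)
  list(H = H, Z = Z, p = pnorm(Z, lower.tail = FALSE))
}

#' Autocorrelation table for all genes
#'
#' Applies [local_autocorrelation()] to every gene and assembles the
#' selection table. The log-normalized expression range (`log_range`) is
#' recorded per gene; BH adjustment is computed across the genes passing
#' the range filter only (others carry `NA`).
#'
#' @param weights symmetric weight matrix from [neighbor_weights()].
#' @param norm normalization result or cells x genes matrix of
#'   log-normalized expression.
#' @param range_min genes with `log_range <= range_min` are excluded from
#'   the FDR universe (default 1).
#' @param latent_label descriptor of the latent space used (metadata).
#' @return data frame `gene`, `H`, `Z`, `p`, `fdr`, `log_range`,
#'   `range_pass`.
#' @export
autocorr_all <- function(weights, norm, range_min = 1,
                         latent_label = "latent") {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  n_genes <- ncol(vals)
  H <- Z <- p <- numeric(n_genes)
  # standardize all genes at once, then batch the quadratic forms
  mu <- colMeans(vals)
  v <- colMeans(sweep(vals, 2, mu)^2)
  rng <- apply(vals, 2, function(x) diff(range(x)))
  ok <- v > 0
  X <- sweep(vals[, ok, drop = FALSE], 2, mu[ok])
  X <- sweep(X, 2, sqrt(v[ok]), "/")
  WX <- as.matrix(weights %*% X)
  H[ok] <- colSums(X * WX) / 2
  varH <- sum(weights@x^2) / 2
  Z[ok] <- H[ok] / sqrt(varH)
  p[ok] <- pnorm(Z[ok], lower.tail = FALSE)
  p[!ok] <- 1
  tab <- data.frame(gene = colnames(vals), H = H, Z = Z, p = p,
                    fdr = NA_real_, log_range = rng,
                    range_pass = rng > range_min,
                    latent = latent_label, stringsAsFactors = FALSE)
  tab$fdr[tab$range_pass] <- p.adjust(tab$p[tab$range_pass], "BH")
  tab
}

#' Permutation null for the autocorrelation statistic
#'
#' Recomputes `H` over `n_perm` random permutations of the cell labels and
#' returns the empirical z-score and one-sided p-value of the observed
#' statistic. Serves as the oracle bounding the analytic normal null.
#'
#' @param weights symmetric weight matrix.
#' @param x per-cell expression of one gene.
#' @param n_perm permutations (at least 100).
#' @param seed integer seed.
#' @return list `H`, `z`, `p`, `perm_mean`, `perm_sd`.
#' @export
permutation_null <- function(weights, x, n_perm = 1000, seed = 0) {
  if (n_perm < 100) stopf("n_perm must be at least 100")
  set.seed(seed)
  obs <- local_autocorrelation(weights, x)
  if (obs$Z == 0 && obs$H == 0 && stats::var(x) == 0)
    return(list(H = 0, z = 0, p = 1, perm_mean = 0, perm_sd = 0))
  v <- stats::var(x) * (length(x) - 1) / length(x)
  zx <- (x - mean(x)) / sqrt(v)
  hp <- vapply(seq_len(n_perm), function(i) {
    xp <- zx[sample.int(length(zx))]
    as.numeric(Matrix::crossprod(xp, weights %*% xp)) / 2
  }, numeric(1))
  sdp <- stats::sd(hp)
  z <- if (sdp == 0) 0 else (obs$H - mean(hp)) / sdp
  list(H = obs$H, z = z, p = (1 + sum(hp >= obs$H)) / (1 + n_perm),
       perm_mean = mean(hp), perm_sd = sdp)
}

#' Select spatially informative genes
#'
#' Excludes genes whose log-normalized expression range is at most
#' `range_min` (inclusive exclusion), then keeps genes with
#' `fdr < fdr_max` and `Z >= z_min`. `z_min = "knee"` instead derives the
#' threshold as the knee point of the descending sorted Z curve.
#'
#' @param results table from [autocorr_all()].
#' @param z_min numeric Z threshold (inclusive, default 10) or `"knee"`.
#' @param fdr_max FDR cutoff (strict `<`, default 1e-5).
#' @param range_min expression-range cutoff (default 1).
#' @return `results` with a logical `selected` column and attributes
#'   `z_min` (the threshold applied) and `z_min_rule`.
#' @export
select_spatial_genes <- function(results, z_min = 10, fdr_max = 1e-5,
                                 range_min = 1) {
  rule <- if (identical(z_min, "knee")) "knee" else "fixed"
  if (rule == "knee") {
    zs <- sort(results$Z, decreasing = TRUE)
    ki <- knee_point(seq_along(zs), zs)
    z_min <- zs[ki]
  }
  sel <- results$range_pass & !is.na(results$fdr) &
    results$fdr < fdr_max & results$Z >= z_min
  if (!any(sel)) warning("no genes selected")
  results$selected <- sel
  attr(results, "z_min") <- z_min
  attr(results, "z_min_rule") <- rule
  results
}
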