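#' Diffusion-based expression smoothing
#'
#' Builds a row-stochastic Markov matrix on the latent space with an
#' adaptive Gaussian kernel (small k) and applies `t` diffusion steps to
#' the expression matrix: `out = P^t x`. Used only for trend fitting and
#' display, never for test statistics.
#'
#' @param norm normalization result or cells x genes matrix.
#' @param latent cells x dims latent space (embedding list accepted).
#' @param k neighbours for the smoothing kernel (default 5).
#' @param t diffusion steps (default 3); `t = 0` returns the input.
#' @return smoothed dense cells x genes matrix.
#' @export
impute_diffusion <- function(norm, latent, k = 5, t = 3) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  if (t < 0) stopf("t must be non-negative")
  if (t == 0) return(vals)
  x <- if (is.list(latent)) latent$values else as_dense(latent)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  graph <- knn_graph(x, k)
  W <- adaptive_kernel_weights(graph, ka = max(1L, floor(k / 3)))
  Matrix::diag(W) <- 1
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1)
    warning(sprintf("smoothing graph has %d components; diffusing within each",
                    comp$no))
  P <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  out <- vals
  for (s in seq_len(t)) out <- as.matrix(P %*% out)
  dimnames(out) <- dimnames(vals)
  out
}

#' Fit a smooth expression trend along a component
#'
#' Min-max normalizes the component to `[0, 1]`, fits a penalized cubic
#' regression spline (GAM, smoothing by GCV) of expression on the
#' component, and predicts at `n_bins` equally spaced bin centers.
#'
#' @param values per-cell expression of one gene.
#' @param component per-cell component (axis) values; must vary.
#' @param n_bins prediction bins (default 500).
#' @param n_knots spline basis dimension (default 8; reduced with a
#'   warning when cells are scarce).
#' @return list with `trend` (length `n_bins`), `bin_centers` on `[0, 1]`,
#'   and the fitted `gam` object.
#' @export
fit_trend <- function(values, component, n_bins = 500, n_knots = 8) {
  if (length(values) < 20) stopf("need at least 20 cells")
  rng <- range(component)
  if (diff(rng) == 0) stopf("component values are constant")
  xs <- (component - rng[1]) / diff(rng)
  bins <- (seq_len(n_bins) - 0.5) / n_bins
  if (stats::var(values) == 0) {
    return(list(trend = rep(values[1], n_bins), bin_centers = bins,
                gam = NULL))
  }
  if (length(values) < 2 * n_knots) {
    n_knots <- max(4, floor(length(values) / 2))
    warning(sprintf("few cells; spline basis reduced to %d", n_knots))
  }
  df <- data.frame(y = values, x = xs)
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = n_knots), data = df,
                   method = "GCV.Cp")
  list(trend = as.numeric(predict(fit, data.frame(x = bins))),
       bin_centers = bins, gam = fit)
}

#' Trend matrix for many genes
#'
#' @param norm normalization result or cells x genes matrix (typically
#'   imputed via [impute_diffusion()]).
#' @param component per-cell axis values.
#' @param genes gene ids to fit (default: all columns).
#' @inheritParams fit_trend
#' @return list (`TrendMatrix`) with `trends` (genes x bins),
#'   `bin_centers`.
#' @export
fit_trends <- function(norm, component, genes = NULL, n_bins = 500,
                       n_knots = 8) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  if (is.null(genes)) genes <- colnames(vals)
  out <- matrix(NA_real_, length(genes), n_bins,
                dimnames = list(genes, NULL))
  bins <- (seq_len(n_bins) - 0.5) / n_bins
  for (g in genes)
    out[g, ] <- fit_trend(vals[, g], component, n_bins, n_knots)$trend
  list(trends = out, bin_centers = bins, n_bins = n_bins)
}

#' Cluster gene trends
#'
#' Z-normalizes each trend across bins, builds a kNN graph among genes
#' under correlation distance (1 - Pearson across bins), and applies
#' [community_detect()]. The number of clusters is emergent.
#'
#' @param trend_matrix result of [fit_trends()] (or a genes x bins
#'   matrix).
#' @param k neighbours among genes (default 20).
#' @param seed clustering seed.
#' @return list with `cluster` (0-based, named by gene), `n_clusters`, and
#'   `flat` (genes with zero-variance trends, assigned singleton clusters).
#' @export
cluster_trends <- function(trend_matrix, k = 20, seed = 0) {
  tr <- if (is.list(trend_matrix)) trend_matrix$trends else
    as_dense(trend_matrix)
  if (nrow(tr) < k + 1) stopf("need at least k + 1 = %d genes", k + 1)
  sds <- apply(tr, 1, stats::sd)
  flat <- which(sds == 0)
  live <- which(sds > 0)
  z <- t(scale(t(tr[live, , drop = FALSE])))
  # correlation distance realized as Euclidean on z-scored rows:
  # d^2 = 2 (n_bins - 1) (1 - r), monotone in (1 - r), so kNN sets match.
  graph <- knn_graph(z, k = min(k, length(live) - 1))
  cl <- community_detect(graph, seed = seed)$cluster
  out <- integer(nrow(tr))
  out[live] <- cl
  if (length(flat))
    out[flat] <- max(cl) + seq_along(flat)
  names(out) <- rownames(tr)
  list(cluster = out, n_clusters = length(unique(out)), flat = flat)
}
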