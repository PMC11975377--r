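# Adaptive Gaussian kernel machinery shared by the diffusion map, the
# absorbing-chain classifier, the autocorrelation weights and imputation.

# Directed affinity a_ij = exp(-d_ij^2 / sigma_i^2) over the kNN edges,
# with sigma_i = distance to the ka-th neighbour (duplicates fall back to
# the smallest positive neighbour distance, then to 1).
adaptive_affinity <- function(graph, ka) {
  n <- graph$n
  sigma <- graph$dist[, ka]
  for (i in which(sigma == 0)) {
    pos <- graph$dist[i, graph$dist[i, ] > 0]
    sigma[i] <- if (length(pos)) min(pos) else 1
  }
  a <- exp(-(graph$dist / sigma)^2)
  Matrix::sparseMatrix(i = rep(seq_len(n), graph$k),
                       j = as.vector(graph$idx), x = as.vector(a),
                       dims = c(n, n))
}

# Symmetrized affinity (A + A^T)/2 with zero diagonal.
adaptive_kernel_weights <- function(graph, ka = max(1L, floor(graph$k / 3))) {
  A <- adaptive_affinity(graph, ka)
  W <- (A + Matrix::t(A)) / 2
  Matrix::diag(W) <- 0
  W
}

#' Diffusion map with adaptive kernel
#'
#' Builds the adaptive Gaussian affinity on the kNN graph, symmetrizes by
#' arithmetic mean, row-normalizes to a Markov transition matrix, and
#' eigendecomposes through the symmetric conjugate
#' \eqn{D^{-1/2} A D^{-1/2}}. The trivial eigenvector (\eqn{\lambda = 1})
#' is discarded; the remaining components are indexed DC0, DC1, ...
#' in decreasing eigenvalue order and unit-normalized.
#'
#' @param x cells x features matrix (log-normalized expression or an
#'   embedding list).
#' @param k nearest neighbours (default 30).
#' @param ka adaptive bandwidth neighbour (default `floor(k/3)`).
#' @param n_eigs eigenpairs to compute including the trivial one (default
#'   41, so a 40-eigenvalue selection window is fully available).
#' @return list with `chain` (sparse transition matrix `P`, kernel
#'   params) and `result`: `eigenvalues` (nontrivial, descending),
#'   `components` (cells x m, columns `DC0`...), `n_selected` from
#'   [eigengap_select()], `orientation` record.
#' @export
diffusion_map <- function(x, k = 30, ka = max(1L, floor(k / 3)),
                          n_eigs = 41) {
  vals <- if (is.list(x)) x$values else as_dense(x)
  if (!all(is.finite(vals))) stopf("input contains non-finite values")
  graph <- knn_graph(vals, k)
  W <- adaptive_kernel_weights(graph, ka)
  Matrix::diag(W) <- 1       # self-affinity keeps the chain aperiodic
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1)
    stopf(paste("kNN graph has %d connected components; diffusion",
                "eigenvalue 1 would be degenerate - subset the cells and",
                "rerun per component"), comp$no)
  d <- Matrix::rowSums(W)
  P <- Matrix::Diagonal(x = 1 / d) %*% W
  S <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% W %*%
    Matrix::Diagonal(x = 1 / sqrt(d))
  S <- (S + Matrix::t(S)) / 2            # guard symmetry to rounding
  n_eigs <- min(n_eigs, nrow(S) - 1)
  eig <- RSpectra::eigs_sym(S, n_eigs, which = "LA")
  ord <- order(eig$values, decreasing = TRUE)
  lam <- eig$values[ord]
  U <- eig$vectors[, ord, drop = FALSE]
  psi <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% U
  psi <- as.matrix(psi)
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  lam <- lam[-1]                          # drop trivial lambda = 1
  psi <- psi[, -1, drop = FALSE]
  colnames(psi) <- paste0("DC", seq_along(lam) - 1)
  rownames(psi) <- rownames(vals)
  result <- list(kind = "diffusion", eigenvalues = lam, components = psi,
                 n_selected = eigengap_select(lam,
                                              window = min(40, length(lam))),
                 orientation = setNames(rep(1, length(lam)), colnames(psi)))
  list(chain = list(P = P, k = k, ka = ka, graph = graph), result = result)
}

#' Select components by the largest eigengap
#'
#' Among the nontrivial eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge ...}
#' restricted to the first `window`, returns the index `i` maximizing
#' \eqn{\lambda_i - \lambda_{i+1}}; components `1..i` are selected.
#'
#' @param eigenvalues nontrivial eigenvalues, descending.
#' @param window search window (default 40).
#' @return number of selected components.
#' @export
eigengap_select <- function(eigenvalues, window = 40) {
  m <- length(eigenvalues)
  if (m < 3) stopf("need at least 3 nontrivial eigenvalues")
  if (m < window) {
    window <- m
    warning(sprintf("fewer eigenvalues than the window; shrunk to %d", window))
  }
  # gaps between consecutive eigenvalues within the window
  gaps <- eigenvalues[seq_len(window - 1)] - eigenvalues[seq_len(window - 1) + 1]
  which.max(gaps)
}

#' Multiscale diffusion embedding
#'
#' Rescales each selected component by \eqn{\lambda / (1 - \lambda)} so
#' Euclidean distance in the embedding approximates diffusion distance
#' across scales.
#'
#' @param result `result` element of [diffusion_map()].
#' @param n_comp number of leading components (default `n_selected`).
#' @return list (`kind = "multiscale"`) with `values` and the scales used.
#' @export
multiscale_embed <- function(result, n_comp = result$n_selected) {
  lam <- result$eigenvalues[seq_len(n_comp)]
  if (any(lam >= 1 - 1e-12))
    stopf("eigenvalue at 1 among selected components (disconnected graph)")
  scale <- lam / (1 - lam)
  vals <- sweep(result$components[, seq_len(n_comp), drop = FALSE], 2,
                scale, "*")
  list(kind = "multiscale", values = vals, scales = scale, n_comp = n_comp)
}

#' Genes correlated with a diffusion component
#'
#' Pearson correlation of every gene's log-normalized expression with the
#' component; two-sided p-values from the t-transform. Returns up to
#' `n_top` genes with `p < p_cutoff`, ranked by absolute correlation, with
#' the correlation sign retained for annotation.
#'
#' @param result `result` element of [diffusion_map()].
#' @param norm normalization result or cells x genes matrix.
#' @param component component name (`"DC0"`) or 1-based index.
#' @param n_top cap on returned genes (default 100).
#' @param p_cutoff p-value cutoff (default 0.01).
#' @return data frame `gene`, `r`, `p`, `sign` ordered by decreasing
#'   `abs(r)`.
#' @export
annotate_component <- function(result, norm, component, n_top = 100,
                               p_cutoff = 0.01) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  ci <- if (is.character(component))
    match(component, colnames(result$components)) else component
  if (is.na(ci) || ci < 1 || ci > ncol(result$components))
    stopf("component out of range")
  psi <- result$components[, ci]
  n <- length(psi)
  sds <- apply(vals, 2, stats::sd)
  r <- rep(0, ncol(vals))
  ok <- sds > 0
  r[ok] <- as.vector(cor(vals[, ok, drop = FALSE], psi))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- ifelse(ok, 2 * pt(-abs(tstat), df = n - 2), 1)
  tab <- data.frame(gene = colnames(vals), r = r, p = p,
                    sign = ifelse(r >= 0, "positive", "negative"))
  tab <- tab[tab$p < p_cutoff, , drop = FALSE]
  tab <- tab[order(-abs(tab$r)), , drop = FALSE]
  utils::head(tab, n_top)
}

#' Orient a diffusion component against an anchor gene set
#'
#' Eigenvector signs are arbitrary; this flips the component so the mean
#' expression of the anchor genes correlates positively with it (for
#' example anchoring DC0 to posterior markers orients it
#' anterior-to-posterior). Idempotent.
#'
#' @param result `result` element of [diffusion_map()].
#' @param component component name or index.
#' @param anchor gene id(s) whose mean expression anchors the positive
#'   direction.
#' @param norm normalization result or cells x genes matrix.
#' @return updated `result` with the component (and its orientation
#'   record) possibly negated.
#' @export
orient_component <- function(result, component, anchor, norm) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  ci <- if (is.character(component))
    match(component, colnames(result$components)) else component
  if (is.na(ci)) stopf("unknown component")
  miss <- setdiff(anchor, colnames(vals))
  if (length(miss)) stopf("anchor gene(s) absent: %s",
                          paste(miss, collapse = ", "))
  expr <- rowMeans(vals[, anchor, drop = FALSE])
  r <- suppressWarnings(cor(expr, result$components[, ci]))
  if (is.na(r) || r == 0) {
    warning("anchor correlation is zero; keeping current sign")
    return(result)
  }
  if (r < 0) {
    result$components[, ci] <- -result$components[, ci]
    result$orientation[ci] <- -result$orientation[ci]
  }
  result
}
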