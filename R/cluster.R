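#' Graph community clustering on a Jaccard-refined kNN graph
#'
#' Re-weights the kNN graph by the Jaccard similarity of neighbourhood
#' sets (each cell's set includes itself) and maximizes modularity with
#' the Louvain algorithm. Deterministic given `seed`.
#'
#' @param graph a [knn_graph()] result.
#' @param seed integer seed for the Louvain pass.
#' @param resolution modularity resolution; 1 is classic modularity,
#'   smaller values favour coarser partitions (for example recovering two
#'   far-separated blobs as exactly two communities).
#' @return list (`ClusterAssignment`) with `cluster` (0-based contiguous
#'   ids), `n_clusters`, and `method` metadata.
#' @export
community_detect <- function(graph, seed = 0, resolution = 1) {
  n <- graph$n
  if (n == 0) stopf("empty graph")
  k <- graph$k
  # membership matrix of neighbourhood sets (self included)
  M <- Matrix::sparseMatrix(i = c(seq_len(n), rep(seq_len(n), k)),
                            j = c(seq_len(n), as.vector(graph$idx)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(M)               # |N(i) inter N(j)|
  p <- pmin(rep(seq_len(n), k), as.vector(graph$idx))
  q <- pmax(rep(seq_len(n), k), as.vector(graph$idx))
  keep <- !duplicated(cbind(p, q))
  p <- p[keep]; q <- q[keep]
  ov <- inter[cbind(p, q)]
  w <- ov / (2 * (k + 1) - ov)
  g <- igraph::graph_from_data_frame(
    data.frame(from = p, to = q, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  com <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                 resolution = resolution)
  memb <- igraph::membership(com)[as.character(seq_len(n))]
  ids <- as.integer(factor(memb, levels = unique(memb[order(seq_len(n))])))
  list(cluster = ids - 1L, n_clusters = length(unique(ids)),
       method = list(algorithm = "jaccard_louvain", k = graph$k,
                     seed = seed, resolution = resolution))
}

#' Clustering stability under neighbourhood-size perturbation
#'
#' Clusters at `k` and at `k` plus/minus each delta, and reports the plain
#' and adjusted Rand index of each perturbed clustering against the base.
#' The run passes when every plain Rand index exceeds `threshold`.
#'
#' @param embedding cells x dims matrix or embedding list.
#' @param k base neighbourhood size.
#' @param deltas absolute k perturbations (default 5 and 10).
#' @param threshold plain-Rand-index pass bar (default 0.8).
#' @param seed clustering seed.
#' @return data frame of comparisons with attribute `pass`.
#' @export
rand_index_stability <- function(embedding, k = 30, deltas = c(5, 10),
                                 threshold = 0.8, seed = 0) {
  x <- if (is.list(embedding)) embedding$values else as_dense(embedding)
  base <- community_detect(knn_graph(x, k), seed = seed)$cluster
  rows <- NULL
  for (d in deltas) for (kk in c(k - d, k + d)) {
    if (kk < 2 || kk >= nrow(x)) next
    alt <- community_detect(knn_graph(x, kk), seed = seed)$cluster
    ri <- rand_indices(base, alt)
    rows <- rbind(rows, data.frame(k = kk, delta = d, rand = ri$rand,
                                   adjusted_rand = ri$adjusted_rand))
  }
  attr(rows, "pass") <- all(rows$rand > threshold)
  rows
}

#' Signed signature score
#'
#' Mean difference in expression of positive and negative gene sets,
#' z-normalized against a random signature of the same sizes: with
#' per-cell all-gene mean \eqn{\mu_c} and variance \eqn{\sigma_c^2}, the
#' two-set score is \eqn{(\bar x_P - \bar x_N) / \sqrt{\sigma_c^2 (1/|P| +
#' 1/|N|)}}; with no negative set the positive mean is compared to
#' \eqn{\mu_c} with null variance \eqn{\sigma_c^2 / |P|}. Cells with zero
#' variance score 0 by convention.
#'
#' @param norm normalization result or cells x genes matrix.
#' @param positive non-empty character vector of positive marker genes.
#' @param negative optional negative marker genes (disjoint from
#'   `positive`).
#' @return numeric per-cell z-score.
#' @export
signature_score <- function(norm, positive, negative = character(0)) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  if (length(positive) == 0) stopf("positive set must be non-empty")
  if (length(intersect(positive, negative)))
    stopf("positive and negative sets overlap")
  miss <- setdiff(c(positive, negative), colnames(vals))
  if (length(miss)) stopf("genes not in universe: %s",
                          paste(miss, collapse = ", "))
  mu <- rowMeans(vals)
  sig2 <- apply(vals, 1, stats::var) * (ncol(vals) - 1) / ncol(vals)
  mp <- rowMeans(vals[, positive, drop = FALSE])
  if (length(negative)) {
    raw <- mp - rowMeans(vals[, negative, drop = FALSE])
    nullvar <- sig2 * (1 / length(positive) + 1 / length(negative))
  } else {
    raw <- mp - mu
    nullvar <- sig2 / length(positive)
  }
  ifelse(nullvar > 0, raw / sqrt(nullvar), 0)
}

#' Build a high-confidence training set from signature scores
#'
#' Per type, the threshold is the 20th percentile of that type's score
#' among cells preliminarily labeled with it; a cell becomes a training
#' example for type `t` iff its score exceeds the type-`t` threshold and
#' is at or below every other type's threshold.
#'
#' @param scores cells x types matrix of signature z-scores.
#' @param labels preliminary per-cell type labels (values must be column
#'   names of `scores`).
#' @param probs threshold percentile (default 0.20).
#' @return list with `label` (per-cell type or `NA` for unlabeled) and the
#'   per-type `thresholds`.
#' @export
build_training_set <- function(scores, labels, probs = 0.20) {
  scores <- as.matrix(scores)
  types <- colnames(scores)
  thr <- vapply(types, function(t) {
    idx <- which(labels == t)
    if (!length(idx)) stopf("type '%s' has no preliminarily labeled cells", t)
    stats::quantile(scores[idx, t], probs = probs, names = FALSE)
  }, numeric(1))
  lab <- rep(NA_character_, nrow(scores))
  above <- sweep(scores, 2, thr, ">")
  one <- rowSums(above) == 1
  lab[one] <- types[apply(above[one, , drop = FALSE], 1, which)]
  empty <- setdiff(types, unique(stats::na.omit(lab)))
  if (length(empty)) stopf("empty training set for type(s): %s",
                           paste(empty, collapse = ", "))
  list(label = lab, thresholds = thr)
}

#' Semi-supervised classification by absorbing Markov chain
#'
#' Builds a row-stochastic transition matrix from symmetrized adaptive
#' Gaussian kernel weights on the kNN graph, makes labeled cells
#' absorbing (absorbing states aggregated by label), and solves
#' \eqn{(I - Q) B = R} for the absorption probabilities of each unlabeled
#' cell into each label class. Each unlabeled cell takes the label with
#' the highest absorption probability; ties break lexicographically.
#'
#' @param graph a [knn_graph()] result.
#' @param labels per-cell labels with `NA` marking unlabeled cells; every
#'   label must appear at least once.
#' @param ka adaptive-kernel bandwidth neighbour (default `floor(k/3)`).
#' @return list with `label` (all cells), `probabilities` (unlabeled cells
#'   x labels) and `unlabeled` indices.
#' @export
absorb_classify <- function(graph, labels, ka = max(1L, floor(graph$k / 3))) {
  n <- graph$n
  lab_levels <- sort(unique(stats::na.omit(labels)))
  if (!length(lab_levels)) stopf("no labeled cells")
  W <- adaptive_kernel_weights(graph, ka)       # symmetric, zero diagonal
  unl <- which(is.na(labels))
  if (!length(unl))
    return(list(label = labels, probabilities = NULL, unlabeled = integer(0)))
  # reachability: every unlabeled cell must connect to a labeled one
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  bad <- unl[!comp[unl] %in% unique(comp[!is.na(labels)])]
  if (length(bad)) stopf("unlabeled cells unreachable from any label: %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  rs <- Matrix::rowSums(W)
  P <- Matrix::Diagonal(x = 1 / rs) %*% W
  Q <- P[unl, unl, drop = FALSE]
  R <- matrix(0, length(unl), length(lab_levels),
              dimnames = list(NULL, lab_levels))
  for (li in seq_along(lab_levels)) {
    cols <- which(labels == lab_levels[li])
    R[, li] <- Matrix::rowSums(P[unl, cols, drop = FALSE])
  }
  B <- as.matrix(Matrix::solve(Matrix::Diagonal(length(unl)) - Q, R))
  out <- labels
  out[unl] <- lab_levels[apply(B, 1, which.max)]
  rownames(B) <- if (!is.null(names(labels))) names(labels)[unl] else unl
  list(label = out, probabilities = B, unlabeled = unl)
}

#' One-vs-rest rank-sum cluster markers
#'
#' Two-sided Wilcoxon rank-sum per gene for each cluster against all other
#' cells, BH-adjusted across genes within cluster, with the log2
#' fold-change of group means.
#'
#' @param norm normalization result or cells x genes matrix.
#' @param clusters per-cell cluster ids.
#' @param pseudo pseudocount for the fold-change (default 1e-9).
#' @return data frame with `cluster`, `gene`, `statistic`, `p`, `fdr`,
#'   `log2fc`.
#' @export
rank_sum_markers <- function(norm, clusters, pseudo = 1e-9) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  if (length(unique(clusters)) < 2) stopf("need at least 2 clusters")
  out <- NULL
  for (cid in sort(unique(clusters))) {
    idx <- clusters == cid
    if (sum(idx) < 2) {
      warning(sprintf("cluster %s is a singleton; skipped", cid))
      next
    }
    tab <- rank_sum_by_gene(vals, idx)
    tab$log2fc <- log2((colMeans(vals[idx, , drop = FALSE]) + pseudo) /
                       (colMeans(vals[!idx, , drop = FALSE]) + pseudo))
    tab$cluster <- cid
    out <- rbind(out, tab[, c("cluster", "gene", "statistic", "p", "fdr",
                              "log2fc")])
  }
  out
}
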