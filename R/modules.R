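#' Ward dendrogram on gene-gene correlation rows
#'
#' Each selected gene's feature vector is its row of the gene-gene Pearson
#' correlation matrix (computed on log-normalized expression, diagonal
#' included); genes are agglomerated by Ward linkage on Euclidean
#' distances between these rows.
#'
#' @param norm normalization result or cells x genes matrix.
#' @param genes selected gene ids (at least 2; constant genes are dropped
#'   with a warning).
#' @return list (`Dendrogram`) with the `hclust` object, `genes` used and
#'   the correlation matrix.
#' @export
correlation_linkage <- function(norm, genes) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  genes <- intersect(genes, colnames(vals))
  if (length(genes) < 2) stopf("need at least 2 genes")
  sub <- vals[, genes, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s) excluded", sum(sds == 0)))
    sub <- sub[, sds > 0, drop = FALSE]
    genes <- colnames(sub)
  }
  cm <- cor(sub)
  hc <- stats::hclust(stats::dist(cm), method = "ward.D2")
  list(hclust = hc, genes = genes, cor_matrix = cm)
}

#' Knee point of a monotone curve
#'
#' Normalizes x and y to `[0, 1]` and returns the index of the point with
#' the maximum perpendicular distance to the chord joining the first and
#' last points; ties break to the smallest index. A flat (straight-line)
#' curve returns the first interior index with a warning.
#'
#' @param x,y coordinates of the curve (at least 3 points).
#' @return integer index of the knee.
#' @export
knee_point <- function(x, y) {
  n <- length(x)
  if (n < 3) stopf("need at least 3 points")
  stopifnot(length(y) == n)
  xr <- diff(range(x)); yr <- diff(range(y))
  xn <- if (xr > 0) (x - min(x)) / xr else rep(0, n)
  yn <- if (yr > 0) (y - min(y)) / yr else rep(0, n)
  dx <- xn[n] - xn[1]; dy <- yn[n] - yn[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) { warning("degenerate chord"); return(2L) }
  d <- abs(dx * (yn[1] - yn) - dy * (xn[1] - xn)) / len
  if (max(d) == 0) {
    warning("curve is a straight line; returning first interior point")
    return(2L)
  }
  which.max(d)
}

# Mean pairwise Pearson correlation within a cluster (singletons: 1).
within_cluster_cor <- function(cm, members) {
  if (length(members) < 2) return(1)
  sub <- cm[members, members]
  mean(sub[upper.tri(sub)])
}

#' Knee-point selection of the module cut
#'
#' For each candidate number of clusters `c` (2 to `max_clusters`),
#' computes the median over clusters of the mean pairwise within-cluster
#' correlation, and picks `c*` at the knee point of that curve. Reports
#' the corresponding linkage height (the cut threshold `D*`) and the
#' achieved median within-cluster correlation.
#'
#' @param dendrogram result of [correlation_linkage()].
#' @param max_clusters candidate cap (default 50).
#' @return list with `n_clusters`, `D_star`, `assignment` (0-based ids by
#'   decreasing size), `achieved_correlation` and the candidate `curve`.
#' @export
select_cut <- function(dendrogram, max_clusters = 50) {
  hc <- dendrogram$hclust
  cm <- dendrogram$cor_matrix
  n <- length(dendrogram$genes)
  cand <- 2:min(max_clusters, n)
  med <- vapply(cand, function(cc) {
    cl <- stats::cutree(hc, k = cc)
    stats::median(vapply(split(seq_len(n), cl), function(m)
      within_cluster_cor(cm, m), numeric(1)))
  }, numeric(1))
  if (diff(range(med)) == 0) {
    warning("flat correlation curve (degenerate input); using 2 clusters")
    ki <- 1L
  } else ki <- knee_point(cand, med)
  cstar <- cand[ki]
  # linkage height realizing exactly cstar clusters
  h <- sort(hc$height, decreasing = TRUE)
  D_star <- if (cstar == 1) h[1] + 1 else mean(h[c(cstar - 1, cstar)])
  list(n_clusters = cstar, D_star = D_star,
       assignment = relabel_by_size(stats::cutree(hc, k = cstar)),
       achieved_correlation = med[ki],
       curve = data.frame(n_clusters = cand, median_within_cor = med))
}

# 0-based cluster ids ordered by decreasing size (stable tie-break).
relabel_by_size <- function(cl) {
  tab <- sort(table(cl), decreasing = TRUE)
  out <- match(as.character(cl), names(tab)) - 1L
  names(out) <- names(cl)
  out
}

#' Cut the module dendrogram at a fixed height
#'
#' Standard dendrogram cut at linkage distance `D`; cluster ids are
#' ordered by decreasing size. Cuts at decreasing `D` are nested.
#'
#' @param dendrogram result of [correlation_linkage()].
#' @param D linkage-height cutoff (`>= 0`).
#' @return integer vector of 0-based cluster ids named by gene.
#' @export
cut_modules <- function(dendrogram, D) {
  if (D < 0) stopf("D must be non-negative")
  cl <- stats::cutree(dendrogram$hclust, h = D)
  relabel_by_size(cl)
}

#' Per-cell score of a gene module
#'
#' One-set signed signature score of the module genes (see
#' [signature_score()]); used to summarize spatially patterned gene
#' clusters per cell.
#'
#' @param norm normalization result or cells x genes matrix.
#' @param module_genes non-empty gene set.
#' @return numeric per-cell z-score.
#' @export
module_score <- function(norm, module_genes) {
  signature_score(norm, positive = module_genes)
}
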