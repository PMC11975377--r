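#' Median-library normalization with log1p
#'
#' Scales each cell to the median library size and applies the natural log
#' with pseudocount 1: \eqn{x_{cg} = \ln(1 + m \, c_{cg} / L_c)} where
#' \eqn{m} is the median library across cells.
#'
#' @param counts sparse cells x genes raw count matrix; every cell must
#'   have a positive library.
#' @return list with dense `values` (cells x genes), `median_lib`, and a
#'   `provenance` record.
#' @export
normalize_median_log1p <- function(counts) {
  lib <- Matrix::rowSums(counts)
  if (any(lib <= 0)) stopf("%d cells have zero library size", sum(lib <= 0))
  m <- stats::median(lib)
  vals <- log1p(as_dense(counts) * (m / lib))
  list(values = vals, median_lib = m,
       provenance = list(norm = "median_libsize", log = "log1p",
                         regressed_programs = character(0)))
}

#' Regress program scores out of the expression matrix
#'
#' Per gene, ordinary least squares of expression on the (centered)
#' program scores with an intercept; returns residuals plus the gene mean,
#' so gene means are preserved exactly. Used as the cell-cycle correction:
#' covariance with the supplied program scores is removed.
#'
#' @param norm normalization result from [normalize_median_log1p()] or a
#'   plain cells x genes matrix.
#' @param program_scores cells x programs numeric matrix.
#' @return object of the same kind as `norm` with adjusted values.
#' @export
regress_out_programs <- function(norm, program_scores) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  S <- as.matrix(program_scores)
  if (!all(is.finite(S))) stopf("program scores must be finite")
  if (nrow(vals) < ncol(S) + 2) stopf("need at least programs + 2 cells")
  Sc <- scale(S, center = TRUE, scale = FALSE)
  qr_s <- qr(Sc)
  if (qr_s$rank < ncol(Sc))
    stopf("rank-deficient program design; collinear programs: %s",
          paste(colnames(S)[qr_s$pivot[seq.int(qr_s$rank + 1, ncol(Sc))]] %||%
                  "unnamed", collapse = ", "))
  beta <- qr.coef(qr_s, vals)
  fitted <- Sc %*% beta
  out <- vals - fitted            # intercept = gene mean since Sc centered
  dimnames(out) <- dimnames(vals)
  if (is.list(norm)) {
    norm$values <- out
    norm$provenance$regressed_programs <-
      c(norm$provenance$regressed_programs,
        colnames(S) %||% paste0("program", seq_len(ncol(S))))
    norm
  } else out
}

#' Variance-stabilized highly-variable-gene selection
#'
#' Ranks genes by the variance of clipped standardized counts: a loess fit
#' (span 0.3) of log10 variance on log10 mean predicts each gene's
#' expected standard deviation; standardized counts are clipped at
#' \eqn{\sqrt{n}} and genes ranked by the variance of the clipped values.
#' Mitochondrial genes, ribosomal genes and genes detected in fewer than
#' `min_cells` cells are excluded before ranking; `always_keep` markers are
#' appended to the selection regardless of rank.
#'
#' @param counts raw cells x genes count matrix.
#' @param n_top number of genes to select (default 3000).
#' @param exclude extra gene ids to exclude (on top of `"^mt-"` and
#'   ribosomal `"^Rp[sl]"` prefixes).
#' @param always_keep marker gene ids appended to the selection.
#' @param min_cells detection floor (default 10 cells).
#' @return list with `selected` gene ids (ranked; markers appended) and the
#'   per-gene `table` (mean, variance, standardized variance, rank).
#' @export
select_hvgs <- function(counts, n_top = 3000, exclude = character(0),
                        always_keep = character(0), min_cells = 10) {
  genes <- colnames(counts)
  dense <- as_dense(counts)
  n <- nrow(dense)
  detected <- colSums(dense > 0)
  drop <- grepl("^mt-", genes, ignore.case = TRUE) |
    grepl("^Rp[sl]", genes) | detected < min_cells | genes %in% exclude
  mu <- colMeans(dense)
  v <- apply(dense, 2, stats::var)
  usable <- !drop & v > 0 & mu > 0
  tab <- data.frame(gene = genes, mean = mu, variance = v,
                    detected = detected, excluded = drop,
                    std_variance = NA_real_, stringsAsFactors = FALSE)
  fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = 0.3,
                      degree = 2)
  sd_exp <- sqrt(10^stats::predict(fit))
  idx <- which(usable)
  clip <- sqrt(n)
  for (j in seq_along(idx)) {
    g <- idx[j]
    z <- (dense[, g] - mu[g]) / sd_exp[j]
    z <- pmin(pmax(z, -clip), clip)
    tab$std_variance[g] <- sum((z - mean(z))^2) / (n - 1)
  }
  # constant (or undetected-mean) genes that survive exclusion rank last
  tab$std_variance[!drop & !usable] <- 0
  ranked <- tab$gene[order(-tab$std_variance, seq_len(ncol(dense)),
                           na.last = TRUE)]
  ranked <- ranked[!is.na(tab$std_variance[match(ranked, tab$gene)])]
  if (n_top > length(ranked))
    warning(sprintf("n_top = %d exceeds %d rankable genes; returning all",
                    n_top, length(ranked)))
  sel <- ranked[seq_len(min(n_top, length(ranked)))]
  sel <- union(sel, intersect(always_keep, genes))
  tab$rank <- match(tab$gene, ranked)
  list(selected = sel, table = tab)
}

#' PCA keeping components to a variance-explained target
#'
#' Centered (unscaled) PCA on the selected-gene submatrix; keeps the
#' smallest number of components whose cumulative variance share reaches
#' `var_target` (default 75%).
#'
#' @param norm normalization result or plain cells x genes matrix.
#' @param hvgs gene ids to use (default: all).
#' @param var_target cumulative variance-share target in (0, 1].
#' @return list (`kind = "pca"`) with `values` (cells x m), per-component
#'   `variance_explained`, `sdev` and `n_selected`.
#' @export
pca_75 <- function(norm, hvgs = NULL, var_target = 0.75) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  if (!is.null(hvgs)) vals <- vals[, intersect(hvgs, colnames(vals)),
                                   drop = FALSE]
  if (nrow(vals) < 2 || ncol(vals) < 2) stopf("need at least 2 cells and genes")
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  if (!any(share > 0)) stopf("zero total variance")
  m <- which(cumsum(share) >= var_target)[1]
  if (is.na(m)) m <- length(share)
  list(kind = "pca", values = pc$x[, seq_len(m), drop = FALSE],
       variance_explained = share[seq_len(m)], sdev = pc$sdev,
       n_selected = m)
}

#' Exact k-nearest-neighbour graph
#'
#' Brute-force Euclidean kNN with self excluded and distance ties broken
#' by ascending cell index, so the graph is fully deterministic.
#'
#' @param embedding cells x dims matrix (or an embedding list with
#'   `values`).
#' @param k neighbours per cell (default 30).
#' @return list (`NeighborGraph`) with `edges` data frame (`src`, `dst`,
#'   `distance`; 1-based), `idx`/`dist` matrices and `k`.
#' @export
knn_graph <- function(embedding, k = 30) {
  x <- if (is.list(embedding)) embedding$values else as_dense(embedding)
  nn <- knn_brute(x, k)
  n <- nrow(x)
  edges <- data.frame(src = rep(seq_len(n), each = k),
                      dst = as.vector(t(nn$idx)),
                      distance = as.vector(t(nn$dist)))
  list(edges = edges, idx = nn$idx, dist = nn$dist, k = k, n = n)
}
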