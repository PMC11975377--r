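#' Per-cell quality-control metrics
#'
#' @param counts sparse cells x genes raw count matrix.
#' @param mito_genes character vector of mitochondrial gene ids (must be a
#'   subset of the gene universe). Defaults to genes prefixed `"mt-"`.
#' @return data frame with one row per cell: `cell`, `library_size`,
#'   `n_genes`, `mito_frac` (0 for all-zero cells by convention).
#' @export
compute_cell_metrics <- function(counts,
                                 mito_genes = grep("^mt-", colnames(counts),
                                                   value = TRUE)) {
  if (nrow(counts) == 0 || ncol(counts) == 0) stopf("empty count matrix")
  if (!all(mito_genes %in% colnames(counts)))
    stopf("mito_genes not all present in the gene universe")
  lib <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  mito <- if (length(mito_genes))
    Matrix::rowSums(counts[, mito_genes, drop = FALSE]) else rep(0, nrow(counts))
  mf <- ifelse(lib > 0, mito / lib, 0)
  data.frame(cell = rownames(counts) %||% seq_len(nrow(counts)),
             library_size = as.numeric(lib), n_genes = as.numeric(ngene),
             mito_frac = as.numeric(mf), stringsAsFactors = FALSE)
}

#' Library-complexity residual filter
#'
#' Ordinary least squares of `log10(n_genes)` on `log10(library_size)`;
#' cells whose observed complexity falls more than 0.1 below the model
#' prediction (residual < -0.1) are flagged for removal. This targets
#' high-library cells dominated by one program (for example
#' mitochondrial-enriched stressed cells).
#'
#' @param metrics data frame from [compute_cell_metrics()].
#' @param cutoff residual cutoff (default 0.1).
#' @return `metrics` with columns `residual` and `complexity_keep` added.
#' @export
fit_complexity_model <- function(metrics, cutoff = 0.1) {
  pos <- metrics$library_size > 0 & metrics$n_genes > 0
  if (sum(pos) < 10) stopf("need at least 10 cells with positive library")
  x <- log10(metrics$library_size[pos])
  y <- log10(metrics$n_genes[pos])
  if (stats::var(x) == 0) stopf("zero-variance predictor: all libraries equal")
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- rep(NA_real_, nrow(metrics))
  res[pos] <- fit$residuals
  metrics$residual <- res
  metrics$complexity_keep <- !is.na(res) & res >= -cutoff
  metrics
}

#' Hard-threshold cell filter
#'
#' Keeps cells with library size strictly above `min_lib` UMIs, a
#' mitochondrial fraction strictly below `max_mito`, and a passing
#' complexity residual.
#'
#' @param metrics data frame from [fit_complexity_model()] (the residual
#'   filter is computed here if absent).
#' @param min_lib library-size threshold (strict `>`, default 1000).
#' @param max_mito mitochondrial-fraction threshold (strict `<`, 0.20).
#' @return character vector of kept cell ids.
#' @export
threshold_filter <- function(metrics, min_lib = 1000, max_mito = 0.20) {
  if (is.null(metrics$complexity_keep)) metrics <- fit_complexity_model(metrics)
  keep <- metrics$library_size > min_lib & metrics$mito_frac < max_mito &
    metrics$complexity_keep
  metrics$cell[keep]
}

# Local maxima indices of a density estimate.
density_modes <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Split cells by library-size bimodality
#'
#' Gaussian kernel density estimate (Silverman's bandwidth) on log10
#' library size. If at least two modes exist, the antimode is the density
#' minimum between the two highest modes; cells above it are assigned
#' `"high"`, below `"low"`. Unimodal distributions yield all `"high"`.
#'
#' @param metrics data frame with `library_size`.
#' @return list with `mode` (per-cell `"high"`/`"low"`), `antimode`
#'   (log10 scale; `NA` when unimodal) and the density object.
#' @export
split_bimodal_library <- function(metrics) {
  lx <- log10(pmax(metrics$library_size, 1))
  if (length(lx) < 100) stopf("need at least 100 cells for the KDE split")
  den <- stats::density(lx, bw = "nrd0")
  peaks <- density_modes(den$y)
  peaks <- peaks[order(den$y[peaks], decreasing = TRUE)]
  unimodal <- list(mode = rep("high", length(lx)), antimode = NA_real_,
                   density = den)
  if (length(peaks) < 2) return(unimodal)
  p2 <- sort(peaks[1:2])
  valley <- seq(p2[1], p2[2])
  anti_y <- min(den$y[valley])
  anti <- den$x[valley[which.min(den$y[valley])]]
  # a genuine antimode dips well below the taller mode (rejects adjacent
  # KDE ripples on one mode) ...
  if (anti_y > 0.5 * max(den$y[peaks[1:2]])) return(unimodal)
  # ... and a genuine second mode carries mass: >= 2% of cells per side
  # (rejects spurious tail bumps)
  frac_low <- mean(lx <= anti)
  if (frac_low < 0.02 || frac_low > 0.98) return(unimodal)
  list(mode = ifelse(lx > anti, "high", "low"), antimode = anti,
       density = den)
}

#' Cluster-level quality reassignment
#'
#' Finely clusters cells (graph communities at small k) and relabels whole
#' clusters as low quality when their mean log10 library size is
#' significantly below the Gaussian fit of the high-quality mode: a
#' two-sided Z-test of the cluster mean against `N(mu_high, sd_high^2 /
#' n_cluster)` at `p < p_cutoff`, requiring the cluster mean to lie below
#' `mu_high`.
#'
#' @param norm normalized matrix (cells x genes) used for clustering.
#' @param metrics metrics data frame aligned with `norm` rows.
#' @param mode per-cell `"high"`/`"low"` assignment from
#'   [split_bimodal_library()].
#' @param k neighbourhood size for the fine clustering (default 8).
#' @param p_cutoff Z-test p-value cutoff (default 1e-10).
#' @param seed clustering seed.
#' @return list with `quality` (per-cell `"high"`/`"low"`), `clusters`,
#'   and the per-cluster test table.
#' @export
cluster_quality_reassignment <- function(norm, metrics, mode, k = 8,
                                         p_cutoff = 1e-10, seed = 0) {
  lx <- log10(pmax(metrics$library_size, 1))
  if (all(mode == "high")) {
    return(list(quality = rep("high", length(mode)), clusters = NULL,
                table = NULL))
  }
  mu_high <- mean(lx[mode == "high"])
  sd_high <- stats::sd(lx[mode == "high"])
  emb <- pca_75(norm)
  graph <- knn_graph(emb$values, k = k)
  cl <- community_detect(graph, seed = seed)$cluster
  qual <- rep("high", length(mode))
  tab <- NULL
  for (cid in sort(unique(cl))) {
    idx <- which(cl == cid)
    if (length(idx) == 1) {           # singleton inherits its own mode
      qual[idx] <- mode[idx]
      next
    }
    m <- mean(lx[idx])
    z <- (m - mu_high) / (sd_high / sqrt(length(idx)))
    p <- 2 * pnorm(-abs(z))
    low <- p < p_cutoff && m < mu_high
    qual[idx] <- if (low) "low" else "high"
    tab <- rbind(tab, data.frame(cluster = cid, n = length(idx), mean = m,
                                 z = z, p = p, low = low))
  }
  list(quality = qual, clusters = cl, table = tab)
}

#' Full quality-control cascade
#'
#' Hard thresholds and complexity filter, KDE bimodality split, and
#' cluster-level reassignment, in the order the analysis applies them.
#'
#' @inheritParams compute_cell_metrics
#' @param min_lib,max_mito,residual_cutoff,k,p_cutoff stage parameters.
#' @param seed clustering seed.
#' @return list with `kept` (cell ids), and the per-cell `metrics` table
#'   (columns `mode`, `quality`, `kept` added).
#' @export
qc_filter <- function(counts,
                      mito_genes = grep("^mt-", colnames(counts), value = TRUE),
                      min_lib = 1000, max_mito = 0.20, residual_cutoff = 0.1,
                      k = 8, p_cutoff = 1e-10, seed = 0) {
  metrics <- compute_cell_metrics(counts, mito_genes)
  metrics <- fit_complexity_model(metrics, cutoff = residual_cutoff)
  pass1 <- metrics$library_size > min_lib & metrics$mito_frac < max_mito &
    metrics$complexity_keep
  metrics$mode <- NA_character_
  metrics$quality <- NA_character_
  sub <- which(pass1)
  if (length(sub) >= 100) {
    split <- split_bimodal_library(metrics[sub, ])
    norm <- normalize_median_log1p(counts[sub, , drop = FALSE])
    reassigned <- cluster_quality_reassignment(norm$values, metrics[sub, ],
                                               split$mode, k = k,
                                               p_cutoff = p_cutoff,
                                               seed = seed)
    metrics$mode[sub] <- split$mode
    metrics$quality[sub] <- reassigned$quality
  } else {
    metrics$mode[sub] <- "high"
    metrics$quality[sub] <- "high"
  }
  metrics$kept <- pass1 & metrics$quality == "high" & !is.na(metrics$quality)
  list(kept = metrics$cell[metrics$kept], metrics = metrics)
}

#' Downsample cells to a common depth
#'
#' Cells with library above `target` have UMIs subsampled without
#' replacement (hypergeometric across genes) to exactly `target`; cells at
#' or below `target` are unchanged.
#'
#' @param counts sparse cells x genes count matrix.
#' @param target depth (default 1000).
#' @param seed integer seed.
#' @return downsampled sparse matrix of the same shape.
#' @export
downsample_counts <- function(counts, target = 1000, seed = 0) {
  if (target < 1) stopf("target must be >= 1")
  set.seed(seed)
  dense <- as_dense(counts)
  lib <- rowSums(dense)
  for (i in which(lib > target)) {
    x <- dense[i, ]
    pool <- rep.int(seq_along(x), x)
    keep <- sample(pool, target)
    dense[i, ] <- tabulate(keep, nbins = length(x))
  }
  out <- Matrix::Matrix(dense, sparse = TRUE)
  dimnames(out) <- dimnames(counts)
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Rank-sum differential expression between quality groups
#'
#' Two-sided Wilcoxon rank-sum per gene on raw downsampled counts, with
#' Benjamini-Hochberg correction across genes. Used to check whether the
#' low-library mode is biologically distinct (stress/ribosomal programs).
#'
#' @param counts_high,counts_low raw count matrices downsampled to a common
#'   depth, same gene universe.
#' @return data frame `gene`, `statistic`, `p`, `fdr`, ordered as the gene
#'   universe.
#' @export
rank_sum_quality_degs <- function(counts_high, counts_low) {
  stopifnot(identical(colnames(counts_high), colnames(counts_low)))
  mat <- rbind(as_dense(counts_high), as_dense(counts_low))
  rank_sum_by_gene(mat, c(rep(TRUE, nrow(counts_high)),
                          rep(FALSE, nrow(counts_low))))
}
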