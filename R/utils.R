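# Internal helpers shared across stages.

#' @importFrom Matrix rowSums colSums t crossprod Diagonal sparseMatrix
#' @importFrom stats median sd var cor density loess predict p.adjust
#'   wilcox.test fisher.test t.test pchisq pnorm pt rnbinom rlnorm runif
#'   rnorm quantile prcomp cutree hclust as.dist dist setNames rbinom
#'   aggregate plogis optim na.omit
NULL

# Dense matrix from any supported input; cells in rows, genes in columns.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force exact kNN with deterministic tie-break by ascending index.
# Returns list(idx = n x k matrix of neighbour indices, dist = n x k).
# Self is excluded. Euclidean metric.
knn_brute <- function(x, k) {
  x <- as_dense(x)
  n <- nrow(x)
  if (k >= n) stopf("k = %d must be smaller than the number of points (%d)", k, n)
  g <- x %*% t(x)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    o <- order(di, seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- sqrt(di[o])
  }
  list(idx = idx, dist = dst)
}

# Pair-counting Rand indices between two label vectors.
rand_indices <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  agree <- total + 2 * sum_ij - sum_a - sum_b
  expected <- sum_a * sum_b / total
  ari_den <- (sum_a + sum_b) / 2 - expected
  ari <- if (ari_den == 0) 1 else (sum_ij - expected) / ari_den
  list(rand = agree / total, adjusted_rand = ari)
}

# Two-sided Wilcoxon rank-sum (normal approximation with tie correction)
# applied to every column of `mat` split by logical `in_group`.
rank_sum_by_gene <- function(mat, in_group) {
  mat <- as_dense(mat)
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  stopifnot(n1 > 0, n2 > 0)
  n <- n1 + n2
  p <- numeric(ncol(mat))
  w <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    r <- rank(x)
    wj <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {            # all values tied
      p[j] <- 1; w[j] <- wj; next
    }
    z <- (wj - n1 * n2 / 2) / sqrt(sigma2)
    # continuity correction toward the null
    zc <- sign(z) * max(0, abs(wj - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p[j] <- 2 * pnorm(-abs(zc))
    w[j] <- wj
  }
  data.frame(gene = colnames(mat) %||% seq_len(ncol(mat)),
             statistic = w, p = p, fdr = p.adjust(p, "BH"))
}
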