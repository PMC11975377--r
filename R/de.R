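#' Two-part hurdle differential-expression test for one gene
#'
#' Discrete part: Fisher's exact test on the 2x2 detection table.
#' Continuous part: Welch t-test on `log2(normalized + 1)` among detected
#' cells only (undefined when a group has fewer than 2 detected cells).
#' Combined p by Fisher's method (chi-squared, 4 df) when both parts are
#' defined, otherwise the defined part. The hurdle effect is the
#' difference of group means of `log2(normalized + 1)` over all cells
#' (group A minus group B).
#'
#' @param xa,xb per-cell normalized (not log) expression of the gene in
#'   groups A and B; both non-empty.
#' @return list `p_discrete`, `p_continuous` (`NA` if undefined),
#'   `p_combined`, `effect`, `rate_a`, `rate_b`.
#' @export
hurdle_test <- function(xa, xb) {
  if (!length(xa) || !length(xb)) stopf("both groups must be non-empty")
  da <- xa > 0; db <- xb > 0
  la <- log2(xa + 1); lb <- log2(xb + 1)
  if (!any(da) && !any(db))
    return(list(p_discrete = 1, p_continuous = NA_real_, p_combined = 1,
                effect = 0, rate_a = 0, rate_b = 0))
  tab <- matrix(c(sum(da), sum(!da), sum(db), sum(!db)), 2)
  p_disc <- stats::fisher.test(tab)$p.value
  p_cont <- NA_real_
  if (sum(da) >= 2 && sum(db) >= 2) {
    va <- stats::var(la[da]); vb <- stats::var(lb[db])
    if (va + vb > 0)
      p_cont <- stats::t.test(la[da], lb[db])$p.value
  }
  p_comb <- if (is.na(p_cont)) p_disc else
    pchisq(-2 * (log(p_disc) + log(p_cont)), df = 4, lower.tail = FALSE)
  list(p_discrete = p_disc, p_continuous = p_cont, p_combined = p_comb,
       effect = mean(la) - mean(lb),
       rate_a = mean(da), rate_b = mean(db))
}

#' Hurdle test across genes, with BH correction
#'
#' @param norm_a,norm_b cells x genes matrices of normalized (not log)
#'   expression for the two groups, same gene universe.
#' @return data frame per gene: detection rates, the three p-values,
#'   `fdr` (BH across genes) and `effect`.
#' @export
hurdle_test_all <- function(norm_a, norm_b) {
  a <- as_dense(norm_a); b <- as_dense(norm_b)
  stopifnot(identical(colnames(a), colnames(b)))
  rows <- lapply(seq_len(ncol(a)), function(j) {
    r <- hurdle_test(a[, j], b[, j])
    data.frame(gene = colnames(a)[j], rate_a = r$rate_a, rate_b = r$rate_b,
               p_discrete = r$p_discrete, p_continuous = r$p_continuous,
               p_combined = r$p_combined, effect = r$effect)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_combined, "BH")
  out
}

#' Region-wise hurdle differential expression
#'
#' Runs [hurdle_test_all()] separately within each region (BH within
#' region, matching the reporting convention); midline cells are excluded
#' upstream by the caller.
#'
#' @param norm cells x genes normalized (not log) matrix.
#' @param group per-cell condition labels (exactly two levels; the first
#'   sorted level is "A").
#' @param region per-cell region labels.
#' @return data frame of per-gene results with a `region` column.
#' @export
region_de <- function(norm, group, region) {
  vals <- as_dense(if (is.list(norm)) norm$values else norm)
  lev <- sort(unique(group))
  if (length(lev) != 2) stopf("need exactly two condition levels")
  out <- NULL
  for (rg in sort(unique(region))) {
    ia <- region == rg & group == lev[1]
    ib <- region == rg & group == lev[2]
    if (!any(ia) || !any(ib)) next
    tab <- hurdle_test_all(vals[ia, , drop = FALSE], vals[ib, , drop = FALSE])
    tab$region <- rg
    out <- rbind(out, tab)
  }
  out
}

#' Apply the primary/report effect thresholds
#'
#' A gene is reported iff it passes `fdr < fdr_max` with
#' `|effect| > primary_effect` in at least one region; its reported
#' region set comprises every region with `fdr < fdr_max` and
#' `|effect| > report_effect`. All comparisons are strict.
#'
#' @param results data frame from [region_de()].
#' @param primary_effect primary threshold (default 0.24).
#' @param report_effect secondary threshold (default 0.10).
#' @param fdr_max FDR cutoff (default 0.001).
#' @return `results` restricted to reported gene-region pairs, with
#'   `pass_primary` flagging the qualifying rows.
#' @export
apply_de_thresholds <- function(results, primary_effect = 0.24,
                                report_effect = 0.10, fdr_max = 0.001) {
  sig <- results$fdr < fdr_max
  primary <- sig & abs(results$effect) > primary_effect
  primary_genes <- unique(results$gene[primary])
  keep <- results$gene %in% primary_genes & sig &
    abs(results$effect) > report_effect
  out <- results[keep, , drop = FALSE]
  out$pass_primary <- primary[keep]
  out
}
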