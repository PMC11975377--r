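#!/usr/bin/env Rscript
# Gene expression trends and multi-resolution modules: MAGIC-style
# diffusion imputation (k = 5, t = 3), cubic-spline GAM trends in 500
# bins along the AP axis (non-midline cells) and the ML axis (midline +
# midbrain/r1 cells), trend clustering (k = 20), and Ward modules on the
# gene-gene correlation matrix with a knee-point cut plus coarser/finer
# stringencies. Per-region temporal axes and trends are computed the
# same way along the stage-verified component.

library(cnpaxes)

counts <- read_counts("results/data/atlas")
truth_cells <- read.csv("results/data/atlas/truth_cells.csv")
norm <- normalize_median_log1p(counts)
spatial_genes <- readLines("results/spatial_genes.txt")

late <- which(truth_cells$stage >= 4)
vals <- norm$values[late, ]
dm <- diffusion_map(vals, k = 30)
axes <- identify_axes(dm$result, vals)
res <- axes$result
ms <- multiscale_embed(res)

# region labels for masking, from the classification step
cls <- read.csv("results/classification.csv")
region <- cls$region[match(rownames(vals), cls$cell)]

imputed <- impute_diffusion(vals, ms$values, k = 5, t = 3)
sets <- list(ap = list(mask = region != "midline", axis = axes$ap),
             ml = list(mask = region %in% c("midline", "midbrain_r1"),
                       axis = axes$ml))
for (nm in names(sets)) {
  s <- sets[[nm]]
  genes <- intersect(spatial_genes, colnames(vals))
  tm <- fit_trends(imputed[s$mask, , drop = FALSE],
                   res$components[s$mask, s$axis], genes = genes)
  cl <- cluster_trends(tm, k = 20, seed = 0)
  write.csv(data.frame(gene = rownames(tm$trends), tm$trends),
            sprintf("results/trends_%s.csv", nm), row.names = FALSE)
  write.csv(data.frame(gene = names(cl$cluster), cluster = cl$cluster),
            sprintf("results/trend_clusters_%s.csv", nm),
            row.names = FALSE)
  message(sprintf("%s axis: %d gene trends in %d clusters", nm,
                  nrow(tm$trends), cl$n_clusters))
}

# multi-resolution modules on the spatially informative set
dend <- correlation_linkage(vals, spatial_genes)
cut <- select_cut(dend)
message(sprintf("knee cut: %d modules at D* = %.2f (median within-module r = %.2f)",
                cut$n_clusters, cut$D_star, cut$achieved_correlation))
write.csv(cut$curve, "results/module_knee_curve.csv", row.names = FALSE)
for (r in c(1, 0.6, 0.4)) {
  cl <- cut_modules(dend, r * cut$D_star)
  write.csv(data.frame(gene = names(cl), module = cl),
            sprintf("results/modules_D%.2g.csv", r * cut$D_star),
            row.names = FALSE)
  message(sprintf("  D = %.2f -> %d modules", r * cut$D_star,
                  length(unique(cl))))
}
msc <- sapply(split(dend$genes, cut_modules(dend, cut$D_star)[dend$genes]),
              function(g) module_score(vals, g))
write.csv(data.frame(cell = rownames(vals), msc),
          "results/module_scores.csv", row.names = FALSE)
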