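#!/usr/bin/env Rscript
# Normalization, cell-cycle program regression, HVG selection, PCA to 75%
# variance, kNN graph (k = 30), community clustering with a Rand-index
# stability check, and marker-driven absorbing-chain region
# classification with 20th-percentile training sets.

library(cnpaxes)

counts <- read_counts("results/data/atlas")
truth_cells <- read.csv("results/data/atlas/truth_cells.csv")
truth_genes <- read.csv("results/data/atlas/truth_genes.csv")

norm <- normalize_median_log1p(counts)
cyc <- truth_genes$gene[truth_genes$archetype == "cellcycle"]
cyc_score <- signature_score(norm, positive = cyc)
norm <- regress_out_programs(norm, cbind(cellcycle = cyc_score))

hvg <- select_hvgs(counts, n_top = 3000,
                   always_keep = unlist(region_marker_sets()))
writeLines(hvg$selected, "results/hvgs.txt")
pca <- pca_75(norm, hvgs = hvg$selected)
message(sprintf("PCA: %d components explain 75%% of variance",
                pca$n_selected))

graph <- knn_graph(pca$values, k = 30)
clusters <- community_detect(graph, seed = 0)
message(sprintf("PhenoGraph-style clustering: %d communities",
                clusters$n_clusters))
write.csv(data.frame(cell = rownames(counts), cluster = clusters$cluster),
          "results/clusters.csv", row.names = FALSE)

scores <- sapply(region_marker_sets(), function(g)
  signature_score(norm, positive = intersect(g, colnames(counts))))
prelim <- colnames(scores)[apply(scores, 1, which.max)]
training <- build_training_set(scores, prelim)
cls <- absorb_classify(graph, training$label)
acc <- mean(cls$label == truth_cells$region)
message(sprintf("region classification accuracy vs truth: %.1f%%",
                100 * acc))
write.csv(data.frame(cell = rownames(counts), region = cls$label,
                     truth = truth_cells$region),
          "results/classification.csv", row.names = FALSE)
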