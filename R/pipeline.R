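#' Default pipeline configuration
#'
#' Every stage threshold is a named parameter defaulting to the analysis'
#' published value: library > 1000 UMIs, mito < 20%, complexity residual
#' 0.1, fine-clustering k = 8 with Z-test p < 1e-10, 3000 HVGs, PCA to
#' 75% variance, clustering k = 30, classification k = 30, eigengap
#' within the first 40 eigenvalues, autocorrelation k = 30 with
#' Z >= 10 (or knee-derived), FDR < 1e-5, log-range > 1, imputation
#' k = 5 / t = 3, 500 trend bins, trend clustering k = 20, and module
#' cuts at the knee height with 0.6x and 0.4x refinements (the
#' coarse/intermediate/fine stringencies).
#'
#' @param sim a [sim_config()] describing the synthetic input (ignored
#'   when `input_dir` points at an on-disk MTX dataset).
#' @param input_dir optional directory readable by [read_counts()].
#' @param seed master seed for all stochastic stages.
#' @param ... overrides for any top-level entry.
#' @return nested configuration list (YAML-serializable).
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL, seed = 0,
                            ...) {
  cfg <- list(
    sim = unclass(sim), input_dir = input_dir, seed = seed,
    qc = list(min_lib = 1000, max_mito = 0.20, residual_cutoff = 0.1,
              k = 8, p_cutoff = 1e-10),
    preprocess = list(n_hvgs = 3000, var_target = 0.75, knn_k = 30),
    cluster = list(k = 30),
    classify = list(k = 30, training_percentile = 0.20),
    diffusion = list(k = 30, n_eigs = 41, eigengap_window = 40),
    autocorr = list(k = 30, z_min = "knee", fdr_max = 1e-5, range_min = 1),
    impute = list(k = 5, t = 3),
    trends = list(n_bins = 500, cluster_k = 20),
    modules = list(max_clusters = 50, cut_ratios = c(1, 0.6, 0.4)),
    late_stages = c(4, 5))
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

write_csv0 <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

#' Run the full axis-reconstruction pipeline
#'
#' Executes simulate/ingest, QC, normalization and program regression,
#' HVG/PCA/kNN, community clustering, marker-driven absorbing-chain
#' region classification, per-region temporal diffusion axes, pooled
#' late-stage spatial axes (AP and ML component identification and
#' orientation by markers), autocorrelation gene selection on the AP/ML
#' components and the multiscale space, imputed gene trends with trend
#' clustering, and multi-resolution gene modules. All tables are written
#' as plain CSV under `out_dir` together with a JSON run report echoing
#' the configuration; reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  markers <- region_marker_sets()

  # --- input ---------------------------------------------------------
  if (is.null(cfg$input_dir)) {
    simc <- do.call(sim_config, cfg$sim)
    sim <- simulate_tissue(simc)
    counts <- sim$counts
    truth <- sim$truth
  } else {
    counts <- read_counts(cfg$input_dir)
    truth <- NULL
  }

  # --- qc ------------------------------------------------------------
  qc <- qc_filter(counts, min_lib = cfg$qc$min_lib,
                  max_mito = cfg$qc$max_mito,
                  residual_cutoff = cfg$qc$residual_cutoff,
                  k = cfg$qc$k, p_cutoff = cfg$qc$p_cutoff,
                  seed = cfg$seed)
  write_csv0(qc$metrics, file.path(out_dir, "qc_metrics.csv"))
  kept <- counts[qc$kept, , drop = FALSE]

  # --- preprocess ----------------------------------------------------
  norm <- normalize_median_log1p(kept)
  cycle_genes <- intersect(colnames(kept),
                           if (!is.null(truth))
                             truth$genes$gene[truth$genes$archetype ==
                                                "cellcycle"]
                           else character(0))
  if (length(cycle_genes) >= 2) {
    cyc_score <- signature_score(norm, positive = cycle_genes)
    norm <- regress_out_programs(norm, cbind(cellcycle = cyc_score))
  }
  hvg <- select_hvgs(kept, n_top = cfg$preprocess$n_hvgs,
                     always_keep = unlist(markers))
  writeLines(hvg$selected, file.path(out_dir, "hvgs.txt"))
  pca <- pca_75(norm, hvgs = hvg$selected,
                var_target = cfg$preprocess$var_target)
  write_csv0(data.frame(cell = rownames(kept), pca$values),
             file.path(out_dir, "pca.csv"))
  graph <- knn_graph(pca$values, k = cfg$preprocess$knn_k)

  # --- clustering + classification -----------------------------------
  clusters <- community_detect(graph, seed = cfg$seed)
  write_csv0(data.frame(cell = rownames(kept), cluster = clusters$cluster),
             file.path(out_dir, "clusters.csv"))
  scores <- sapply(markers, function(g)
    signature_score(norm, positive = intersect(g, colnames(kept))))
  prelim <- colnames(scores)[apply(scores, 1, which.max)]
  training <- build_training_set(scores, prelim,
                                 probs = cfg$classify$training_percentile)
  cls <- absorb_classify(graph, training$label)
  region <- cls$label
  write_csv0(data.frame(cell = rownames(kept), region = region),
             file.path(out_dir, "classification.csv"))

  # --- temporal axes: per-region DC0 ---------------------------------
  temporal <- list()
  stage_meta <- if (!is.null(truth))
    truth$cells$stage[match(rownames(kept), truth$cells$cell)] else NULL
  for (rg in c("forebrain", "midbrain_r1", "hindbrain")) {
    idx <- which(region == rg)
    if (length(idx) < cfg$diffusion$k + 2) next
    dm <- diffusion_map(norm$values[idx, , drop = FALSE],
                        k = cfg$diffusion$k, n_eigs = cfg$diffusion$n_eigs)
    ta <- if (!is.null(stage_meta))
      temporal_axis(dm$result, stage_meta[idx]) else
      list(component = "DC0", values = dm$result$components[, 1],
           stage_cor = NA_real_)
    temporal[[rg]] <- list(cells = rownames(kept)[idx], result = dm$result,
                           axis = ta)
    write_csv0(data.frame(cell = rownames(kept)[idx], time_axis = ta$values),
               file.path(out_dir, sprintf("temporal_axis_%s.csv", rg)))
  }

  # --- pooled late-stage spatial axes --------------------------------
  late_cells <- if (!is.null(truth))
    truth$cells$cell[truth$cells$stage %in% cfg$late_stages] else
      rownames(kept)
  sp_idx <- which(rownames(kept) %in% late_cells)
  sp_norm <- norm$values[sp_idx, , drop = FALSE]
  dm <- diffusion_map(sp_norm, k = cfg$diffusion$k,
                      n_eigs = cfg$diffusion$n_eigs)
  axes <- identify_axes(dm$result, sp_norm, markers)
  res <- axes$result
  write_csv0(data.frame(cell = rownames(sp_norm),
                        res$components[, seq_len(res$n_selected),
                                       drop = FALSE]),
             file.path(out_dir, "diffusion.csv"))
  write_csv0(data.frame(component = colnames(res$components),
                        eigenvalue = res$eigenvalues),
             file.path(out_dir, "eigenvalues.csv"))
  for (dc in c(axes$ap, axes$ml)) {
    ann <- annotate_component(res, sp_norm, dc)
    write_csv0(ann, file.path(out_dir, sprintf("annotation_%s.csv", dc)))
  }

  # --- autocorrelation gene selection --------------------------------
  ms <- multiscale_embed(res)
  latents <- list()
  latents[[axes$ap]] <- res$components[, axes$ap, drop = FALSE]
  latents[[axes$ml]] <- res$components[, axes$ml, drop = FALSE]
  latents[["multiscale"]] <- ms$values
  autocorr <- list()
  for (nm in names(latents)) {
    w <- neighbor_weights(latents[[nm]], k = cfg$autocorr$k)
    tab <- autocorr_all(w, sp_norm, range_min = cfg$autocorr$range_min,
                        latent_label = nm)
    tab <- select_spatial_genes(tab, z_min = cfg$autocorr$z_min,
                                fdr_max = cfg$autocorr$fdr_max,
                                range_min = cfg$autocorr$range_min)
    autocorr[[nm]] <- tab
    write_csv0(tab, file.path(out_dir, sprintf("autocorr_%s.csv", nm)))
  }
  # spatially informative set = union over the per-axis and multiscale
  # analyses, as the published gene set combines all three
  spatial_genes <- unique(unlist(lapply(autocorr, function(tab)
    tab$gene[tab$selected])))

  # --- trends --------------------------------------------------------
  sp_region <- region[sp_idx]
  imputed <- impute_diffusion(sp_norm, ms$values, k = cfg$impute$k,
                              t = cfg$impute$t)
  trend_sets <- list(
    ap = list(cells = sp_region != "midline", axis = axes$ap),
    ml = list(cells = sp_region %in% c("midline", "midbrain_r1"),
              axis = axes$ml))
  trends <- list()
  for (nm in names(trend_sets)) {
    ts <- trend_sets[[nm]]
    genes <- autocorr[[ts$axis]]$gene[autocorr[[ts$axis]]$selected]
    if (length(genes) < cfg$trends$cluster_k + 1) next
    tm <- fit_trends(imputed[ts$cells, , drop = FALSE],
                     res$components[ts$cells, ts$axis], genes = genes,
                     n_bins = cfg$trends$n_bins)
    cl <- cluster_trends(tm, k = cfg$trends$cluster_k, seed = cfg$seed)
    trends[[nm]] <- list(trends = tm, clusters = cl)
    write_csv0(data.frame(gene = rownames(tm$trends), tm$trends),
               file.path(out_dir, sprintf("trends_%s.csv", nm)))
    write_csv0(data.frame(gene = names(cl$cluster), cluster = cl$cluster),
               file.path(out_dir, sprintf("trend_clusters_%s.csv", nm)))
  }

  # --- gene modules --------------------------------------------------
  modules <- NULL
  if (length(spatial_genes) >= 3) {
    dend <- correlation_linkage(sp_norm, spatial_genes)
    cut <- select_cut(dend, max_clusters = cfg$modules$max_clusters)
    cuts <- lapply(cfg$modules$cut_ratios, function(r)
      cut_modules(dend, r * cut$D_star))
    names(cuts) <- sprintf("D%.2g", cfg$modules$cut_ratios * cut$D_star)
    for (nm in names(cuts))
      write_csv0(data.frame(gene = names(cuts[[nm]]), module = cuts[[nm]]),
                 file.path(out_dir, sprintf("modules_%s.csv", nm)))
    write_csv0(cut$curve, file.path(out_dir, "module_knee_curve.csv"))
    msc <- sapply(split(names(cuts[[1]]), cuts[[1]]), function(g)
      module_score(list(values = sp_norm), g))
    write_csv0(data.frame(cell = rownames(sp_norm), msc),
               file.path(out_dir, "module_scores.csv"))
    modules <- list(dendrogram = dend, selected_cut = cut, cuts = cuts)
  }

  # --- run report ----------------------------------------------------
  report <- list(package = "cnpaxes",
                 version = as.character(utils::packageVersion("cnpaxes")),
                 config = cfg, n_cells_in = nrow(counts),
                 n_cells_kept = nrow(kept),
                 axes = list(ap = axes$ap, ml = axes$ml),
                 n_selected_components = res$n_selected,
                 n_spatial_genes = length(spatial_genes))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(counts = counts, truth = truth, qc = qc, norm = norm,
                 pca = pca, clusters = clusters, region = region,
                 temporal = temporal, spatial = list(result = res,
                                                     axes = axes,
                                                     cells = sp_idx),
                 autocorr = autocorr, trends = trends, modules = modules))
}

#' Identify and orient the temporal diffusion component
#'
#' Among the leading components of a per-region diffusion map, returns the
#' one most correlated with the observed sample stage, oriented so stage
#' increases along it. This formalizes the verification that the top
#' component of each region associates with somite stage.
#'
#' @param result `result` element of [diffusion_map()].
#' @param stage per-cell stage metadata (numeric).
#' @param n_search leading components searched (default 5).
#' @return list with `component` (name), `values` (oriented per-cell axis)
#'   and `stage_cor` (Spearman correlation with stage).
#' @export
temporal_axis <- function(result, stage, n_search = 5) {
  n_search <- min(n_search, ncol(result$components))
  comp <- result$components[, seq_len(n_search), drop = FALSE]
  r <- apply(comp, 2, cor, y = stage, method = "spearman")
  i <- which.max(abs(r))
  v <- comp[, i] * sign(r[i])
  list(component = colnames(comp)[i], values = v, stage_cor = abs(r[i]))
}

#' Identify and orient the AP and ML diffusion components
#'
#' Among the eigengap-selected components, the anterior-posterior (AP)
#' axis is the component most correlated (absolute Pearson) with the
#' hindbrain-minus-forebrain marker score contrast, oriented so posterior
#' (hindbrain) markers sit at high values; the mediolateral (ML) axis is
#' the remaining component most correlated with the midline marker score,
#' oriented so the midline sits at low values (lateral positive).
#'
#' @param result `result` element of [diffusion_map()].
#' @param norm cells x genes log-normalized matrix matching the map.
#' @param markers named list with `forebrain`, `hindbrain`, `midline`
#'   gene sets (see [region_marker_sets()]).
#' @param n_search how many leading components to annotate (default: the
#'   eigengap-selected count, or the first 10 if more are available —
#'   marker annotation, not the eigengap, names the axes; the eigengap
#'   governs the multiscale space).
#' @return list with oriented `result` and component names `ap`, `ml`.
#' @export
identify_axes <- function(result, norm, markers = region_marker_sets(),
                          n_search = max(result$n_selected,
                                         min(10, ncol(result$components)))) {
  vals <- if (is.list(norm)) norm$values else as_dense(norm)
  comp <- result$components[, seq_len(n_search), drop = FALSE]
  mscore <- function(g) {
    g <- intersect(g, colnames(vals))
    if (!length(g)) return(rep(0, nrow(vals)))
    rowMeans(vals[, g, drop = FALSE])
  }
  ap_contrast <- mscore(markers$hindbrain) - mscore(markers$forebrain)
  # lateral-minus-midline contrast names the mediolateral component
  mlm <- ml_axis_markers()
  ml_contrast <- mscore(mlm$lateral) - mscore(mlm$midline)
  r_ap <- abs(apply(comp, 2, cor, y = ap_contrast))
  ap <- colnames(comp)[which.max(r_ap)]
  r_ml <- abs(apply(comp, 2, cor, y = ml_contrast))
  r_ml[ap] <- -Inf
  ml <- colnames(comp)[which.max(r_ml)]
  result <- orient_component(result, ap, markers$hindbrain, vals)
  # orient ML so the midline sits low (lateral markers positive)
  lat <- intersect(mlm$lateral, colnames(vals))
  result <- if (length(lat)) orient_component(result, ml, lat, vals) else {
    r <- orient_component(result, ml, markers$midline, vals)
    r$components[, ml] <- -r$components[, ml]
    r$orientation[ml] <- -r$orientation[ml]
    r
  }
  list(result = result, ap = ap, ml = ml)
}
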