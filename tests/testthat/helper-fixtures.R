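# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), .fixtures)
  get(name, envir = .fixtures)
}

# The default study fixture: 3000 cells, 2000 genes, amplitude 4, seed 0.
default_sim <- function() cached("sim", simulate_tissue(sim_config(seed = 0)))

default_norm <- function() cached("norm", {
  normalize_median_log1p(default_sim()$counts)
})

# Spatial analysis surface: pooled late-stage cells, diffusion axes.
late_spatial <- function() cached("spatial", {
  sim <- default_sim()
  norm <- default_norm()
  late <- which(sim$truth$cells$stage >= 4)
  dm <- diffusion_map(norm$values[late, , drop = FALSE], k = 30)
  axes <- identify_axes(dm$result, norm$values[late, , drop = FALSE])
  list(late = late, chain = dm$chain, result = axes$result,
       ap = axes$ap, ml = axes$ml,
       truth = sim$truth$cells[late, , drop = FALSE],
       norm = norm$values[late, , drop = FALSE])
})

# Small bimodal-quality fixture for the QC cascade.
qc_sim <- function() cached("qc_sim", {
  simulate_tissue(sim_config(n_cells = 200, n_stages = 6, n_genes = 800,
                             lowq_frac = 0.2, seed = 11))
})

# Deterministic small Gaussian blobs for clustering tests.
make_blobs <- function(n_per = 200, centers = rbind(c(0, 0), c(8, 8)),
                       sd = 1, seed = 42) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = x, label = rep(seq_len(nrow(centers)), each = n_per))
}
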