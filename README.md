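# cnpaxes

Reconstruction of spatial (anterior–posterior, mediolateral) and
temporal axes of gene expression from droplet single-cell RNA-seq of the
embryonic mouse cranial neural plate — for developmental biologists and
computational groups who want the full published-style analysis chain as
tested, reusable R functions rather than a one-off notebook.

Dissociation destroys tissue geometry, but in the cranial neural plate
cell states are dominated by position and stage, so the axes can be
rebuilt from expression alone. The package implements:

* **QC cascade** — library > 1000 UMIs (strict), mitochondrial
  fraction < 20% (strict), a complexity filter on the residual of
  log10(genes) ~ log10(library) at 0.1, a KDE bimodality split of
  library sizes, and cluster-level Z-test reassignment (k = 8,
  p < 1e-10).
* **Preprocessing** — median-library log1p normalization, cell-cycle
  program regression, seurat_v3-style variance-stabilized HVG ranking,
  PCA to 75% variance, exact kNN graphs (k = 30) with deterministic
  tie-breaks.
* **Clustering & classification** — Jaccard/Louvain communities with
  Rand-index stability checks; signed signature scores
  (z-normalized against a random-signature null); 20th-percentile
  training sets; absorbing-Markov-chain label propagation solving
  (I − Q)B = R.
* **Diffusion axes** — adaptive-kernel diffusion maps
  (a_ij = exp(−d_ij²/σ_i²), σ_i the distance to the ⌊k/3⌋-th
  neighbour), eigengap component selection within the first 40
  eigenvalues, multiscale embedding ψ·λ/(1−λ), and marker-driven axis
  annotation/orientation (DC0 = AP, DC2 = ML, per-region stage-verified
  temporal axes).
* **Spatial gene selection** — the graph-weighted local autocorrelation
  statistic H = Σ_{i<j} w_ij x_i x_j with its Gaussian analytic null
  (Z = H/√Σw²), a permutation oracle, and selection by log-range > 1,
  FDR < 1e-5 and a Z threshold (fixed Z ≥ 10 or knee-point).
* **Trends & modules** — diffusion imputation (k = 5, t = 3), penalized
  cubic-spline GAM trends in 500 bins, trend clustering (k = 20), and
  multi-resolution Ward modules on the gene–gene correlation matrix
  with a knee-point-calibrated cut and coarser/finer stringencies.
* **Perturbation DE** — a two-part hurdle test (Fisher exact on
  detection + Welch t on detected cells, Fisher-combined) with the
  published reporting rules (FDR < 0.001, |effect| > 0.24 primary,
  > 0.10 per region).
* **Synthetic tissue generator** — negative-binomial counts over
  planted AP-step / ML-gradient / two-dimensional / temporal / cycle /
  stress archetypes with full ground truth, so every stage above is
  testable offline.

## Worked example

```r
library(cnpaxes)

sim  <- simulate_tissue(sim_config(seed = 0))    # 3000 cells x 2000 genes
norm <- normalize_median_log1p(sim$counts)

late <- which(sim$truth$cells$stage >= 4)        # pooled late stages
dm   <- diffusion_map(norm$values[late, ], k = 30)
axes <- identify_axes(dm$result, norm$values[late, ])

cor(axes$result$components[, axes$ap],
    sim$truth$cells$ap[late], method = "spearman")
#> [1] 0.9286
cor(axes$result$components[, axes$ml],
    abs(sim$truth$cells$ml[late]), method = "spearman")
#> [1] 0.9011
```

DC0 orders cells anterior → posterior with Spearman 0.93 against the
generator's hidden AP coordinate, and DC2 orders them midline → lateral
at 0.90 — the axes are recovered from counts alone. Running the
selection and classification stages on the same fixture
(`analysis/03_preprocess_classify.R`, `analysis/05_spatial_genes.R`)
prints:

```
region classification accuracy vs truth: 98.3%
union: 461 genes; sensitivity 1.000, FDP 0.002
```

i.e. the absorbing-chain classifier recovers the four regions at 98.3%,
and the autocorrelation screen finds every planted spatially patterned
gene with 0.2% false discoveries.

The `analysis/` directory holds the numbered drivers for the complete
study — simulation, QC, preprocessing/classification, spatial axes,
spatial genes, trends/modules, differential expression — each a thin
narrative script over the package functions that writes its tables under
`results/`. Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

`run_pipeline(pipeline_config(), out_dir)` executes the same chain in
one call and writes a JSON run report; reruns with the same
configuration are byte-identical.

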