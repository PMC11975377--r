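#' Configuration for the patterned-tissue simulator
#'
#' Builds the parameter set for [simulate_tissue()]. The defaults describe a
#' desk-scale analogue of a staged cranial neural plate atlas: six
#' consecutive stages, cells laid out on a unit anterior-posterior (AP)
#' coordinate and a signed mediolateral (ML) coordinate, and genes drawn
#' from step/gradient/temporal archetypes on top of a negative-binomial
#' noise model with log-normal library sizes.
#'
#' @param n_cells cells simulated per stage.
#' @param n_stages number of developmental stages (stage ids `0..n_stages-1`).
#' @param n_genes total genes, including reserved mitochondrial ids.
#' @param frac_ap,frac_ml,frac_2d,frac_temporal fractions of genes assigned
#'   to AP step, ML gradient, two-dimensional (AP x ML product) and temporal
#'   archetypes. Remaining genes (after the small fixed cell-cycle and
#'   stress programs) are unpatterned (`null`). Must sum to at most 1.
#' @param frac_cellcycle,frac_stress fractions for the shared cell-cycle
#'   program and the stress program used by the low-quality mode.
#' @param amplitude fold-change of a fully "on" patterned mean over the
#'   baseline; must be positive. `amplitude = 1` means no pattern.
#' @param dispersion negative-binomial size parameter \eqn{\theta} shared by
#'   all genes (variance \eqn{\mu + \mu^2/\theta}).
#' @param lib_mu,lib_sigma meanlog and sdlog of the log-normal per-cell
#'   library size.
#' @param lowq_frac fraction of cells converted to the low-quality mode by
#'   [inject_low_quality_cells()]; 0 disables injection.
#' @param midline_halfwidth half-width of the midline band: cells with
#'   `|ml| <` this value are midline regardless of AP position.
#' @param seed integer seed; all randomness flows through it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 500, n_stages = 6, n_genes = 2000,
                       frac_ap = 0.10, frac_ml = 0.08, frac_2d = 0.05,
                       frac_temporal = 0.08, frac_cellcycle = 0.01,
                       frac_stress = 0.01, amplitude = 4, dispersion = 2,
                       lib_mu = log(42000), lib_sigma = 0.35,
                       lowq_frac = 0, midline_halfwidth = 0.05, seed = 0) {
  fr <- c(frac_ap, frac_ml, frac_2d, frac_temporal, frac_cellcycle, frac_stress)
  if (any(fr < 0) || any(fr > 1))
    stopf("archetype fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stopf("archetype fractions sum to %.3f > 1", sum(fr))
  if (n_cells <= 0 || n_genes <= 0) stopf("n_cells and n_genes must be positive")
  if (amplitude <= 0) stopf("amplitude must be positive")
  if (lowq_frac < 0 || lowq_frac >= 1) stopf("lowq_frac must lie in [0, 1)")
  cfg <- list(n_cells = n_cells, n_stages = n_stages, n_genes = n_genes,
              frac_ap = frac_ap, frac_ml = frac_ml, frac_2d = frac_2d,
              frac_temporal = frac_temporal, frac_cellcycle = frac_cellcycle,
              frac_stress = frac_stress, amplitude = amplitude,
              dispersion = dispersion, lib_mu = lib_mu, lib_sigma = lib_sigma,
              lowq_frac = lowq_frac, midline_halfwidth = midline_halfwidth,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# The 11 AP step archetypes: indicators over contiguous AP intervals built
# from the forebrain/midbrain-r1/hindbrain thirds and their halves/unions.
ap_step_intervals <- function() {
  list(c(0, 1/3), c(1/3, 2/3), c(2/3, 1),         # the three regions
       c(0, 2/3), c(1/3, 1),                       # two-region unions
       # staggered sub-region domains (nested/offset AP windows, the way
       # rostral domains and rhombomere-restricted genes tile the axis)
       c(0, 1/6), c(1/6, 1/2), c(0.25, 0.75),
       c(1/2, 5/6), c(0.6, 0.9), c(5/6, 1))
}

# Region labels from tissue coordinates; midline overrides the AP thirds.
region_from_coords <- function(ap, ml, midline_halfwidth = 0.05) {
  reg <- ifelse(ap < 1/3, "forebrain",
                ifelse(ap < 2/3, "midbrain_r1", "hindbrain"))
  reg[abs(ml) < midline_halfwidth] <- "midline"
  reg
}

#' Region marker sets planted by the simulator
#'
#' Named gene lists mirroring the canonical forebrain (*Otx2*, *Six3*),
#' midbrain/r1 (*En1* ... *Wnt1*), hindbrain (*Egr2* ... *Hoxb3*) and
#' ventral midline (*Foxa2*, *Nkx6-1*, *Ptch1*, *Shh*) markers. The
#' simulator names its first AP-step and midline-gradient genes after these
#' so that marker-driven classification is exercisable on synthetic data.
#'
#' @return named list of character vectors of gene names.
#' @export
region_marker_sets <- function() {
  list(forebrain   = c("Otx2", "Six3"),
       midbrain_r1 = c("En1", "En2", "Fgf8", "Pax2", "Pax5", "Pax8", "Wnt1"),
       hindbrain   = c("Egr2", "Gbx1", "Gbx2", "Hoxa2", "Hoxb2", "Hoxb3"),
       midline     = c("Foxa2", "Nkx6-1", "Ptch1", "Shh"))
}

#' Mediolateral axis marker sets planted by the simulator
#'
#' Laterally expressed genes (*Pax3*, *Pax7*, *Tfap2a*, *Zic1*) and
#' ventral midline markers; the lateral-minus-midline contrast annotates
#' and orients the mediolateral diffusion component.
#'
#' @return named list with `lateral` and `midline` gene name vectors.
#' @export
ml_axis_markers <- function() {
  list(lateral = c("Pax3", "Pax7", "Tfap2a", "Zic1"),
       midline = region_marker_sets()$midline)
}

# Archetype multiplier f_g(ap, ml, stage, cyc) on [1, amplitude].
archetype_factor <- function(archetype, param, ap, ml, stage, cyc,
                             amplitude, n_stages) {
  a <- amplitude - 1
  switch(archetype,
    null = rep(1, length(ap)),
    stress = rep(1, length(ap)),
    cellcycle = 1 + a * cyc,
    ap_step = {
      iv <- ap_step_intervals()[[param]]
      ind <- as.numeric(ap >= iv[1] & ap < iv[2] | (iv[2] == 1 & ap == 1))
      # AP-patterned programs are not recapitulated in the ventral
      # midline: gate the step off inside the floor-plate band
      1 + a * ind * (1 - plogis((0.05 - abs(ml)) / 0.01))
    },
    ml_gradient_up = {
      ctr <- param$center %||% 0.45; scl <- param$scale %||% 0.15
      1 + a * plogis((abs(ml) - ctr) / scl)
    },
    ml_gradient_down = {
      ctr <- param$center %||% 0.25; scl <- param$scale %||% 0.10
      1 + a * plogis((ctr - abs(ml)) / scl)
    },
    two_dim = {
      iv <- ap_step_intervals()[[param$ap]]
      ind <- as.numeric(ap >= iv[1] & ap < iv[2] | (iv[2] == 1 & ap == 1))
      sig <- if (param$ml == "down") plogis((0.25 - abs(ml)) / 0.10)
             else plogis((abs(ml) - 0.45) / 0.15)
      1 + a * ind * sig
    },
    temporal_up = 1 + a * plogis((stage - (n_stages - 1) / 2) / 0.7),
    temporal_down = 1 + a * plogis(((n_stages - 1) / 2 - stage) / 0.7),
    stopf("unknown archetype '%s'", archetype))
}

# Assign archetypes to genes. Mitochondrial ids (1% of genes, "mt-" prefix)
# are always null-patterned housekeeping with elevated base rate.
assign_archetypes <- function(cfg) {
  n <- cfg$n_genes
  n_mito <- max(1L, floor(0.01 * n))
  n_ap <- round(cfg$frac_ap * n)
  n_ml <- round(cfg$frac_ml * n)
  n_2d <- round(cfg$frac_2d * n)
  n_tm <- round(cfg$frac_temporal * n)
  n_cc <- round(cfg$frac_cellcycle * n)
  n_st <- round(cfg$frac_stress * n)
  if (n_mito + n_ap + n_ml + n_2d + n_tm + n_cc + n_st > n ||
      (cfg$frac_ap > 0 && n_ap < length(ap_step_intervals())) ||
      (cfg$frac_ml > 0 && n_ml < 2) ||
      (cfg$frac_temporal > 0 && n_tm < 2) ||
      (cfg$frac_2d > 0 && n_2d < 1) ||
      (cfg$frac_cellcycle > 0 && n_cc < 1) ||
      (cfg$frac_stress > 0 && n_st < 1))
    stopf("n_genes = %d too small to host one gene per archetype", n)
  arch <- rep("null", n)
  param <- vector("list", n)
  i <- n_mito  # genes 1..n_mito reserved mito
  take <- function(k) { r <- seq.int(i + 1, length.out = k); i <<- i + k; r }
  ap_idx <- take(n_ap)
  arch[ap_idx] <- "ap_step"
  param[ap_idx] <- rep(seq_along(ap_step_intervals()), length.out = n_ap)
  ml_idx <- take(n_ml)
  arch[ml_idx] <- rep(c("ml_gradient_up", "ml_gradient_down"),
                      length.out = n_ml)
  td_idx <- take(n_2d)
  arch[td_idx] <- "two_dim"
  param[td_idx] <- lapply(seq_len(n_2d), function(j)
    list(ap = ((j - 1) %% 3) + 1, ml = if (j %% 2 == 0) "down" else "up"))
  tm_idx <- take(n_tm)
  arch[tm_idx] <- rep(c("temporal_up", "temporal_down"), length.out = n_tm)
  cc_idx <- take(n_cc)
  arch[cc_idx] <- "cellcycle"
  st_idx <- take(n_st)
  arch[st_idx] <- "stress"

  name <- sprintf("gene%04d", seq_len(n))
  name[seq_len(n_mito)] <- sprintf("mt-%d", seq_len(n_mito))
  mk <- region_marker_sets()
  # plant marker names on matching archetypes
  fb <- ap_idx[which(unlist(param[ap_idx]) == 1)]
  mb <- ap_idx[which(unlist(param[ap_idx]) == 2)]
  hb <- ap_idx[which(unlist(param[ap_idx]) == 3)]
  ml_dn <- ml_idx[arch[ml_idx] == "ml_gradient_down"]
  plant <- function(slots, nm) {
    u <- seq_len(min(length(slots), length(nm)))
    name[slots[u]] <<- nm[u]
  }
  plant(fb, mk$forebrain)
  plant(mb, mk$midbrain_r1)
  plant(hb, mk$hindbrain)
  plant(ml_dn, mk$midline)
  ml_up <- ml_idx[arch[ml_idx] == "ml_gradient_up"]
  plant(ml_up, ml_axis_markers()$lateral)
  # named midline markers are floor-plate-restricted (sharp sigmoid),
  # unlike the broad mediolateral gradients they sit among
  sharp <- ml_dn[seq_len(min(length(ml_dn), length(mk$midline)))]
  param[sharp] <- rep(list(list(center = 0.05, scale = 0.01)),
                      length(sharp))
  data.frame(gene = name, archetype = arch, mito = seq_len(n) <= n_mito,
             param = I(param), stringsAsFactors = FALSE)
}

#' Simulate a staged, spatially patterned scRNA-seq count matrix
#'
#' Cells receive uniform AP coordinates in `[0, 1]`, signed ML coordinates
#' in `[-1, 1]`, a stage id, a shared cell-cycle activity and a log-normal
#' target library size. Gene means are
#' \eqn{\mu_{cg} = L_c \, p_g f_g(c) / \sum_g p_g f_g(c)} so that each
#' cell's expected library equals its target \eqn{L_c}; counts are
#' negative-binomial with shared size \eqn{\theta}. If `lowq_frac > 0` a
#' low-quality mode is injected via [inject_low_quality_cells()].
#'
#' @param config a [sim_config()].
#' @return list with `counts` (sparse cells x genes dgCMatrix) and `truth`
#'   (list of `cells` and `genes` data frames plus the config); the truth
#'   tables carry per-cell `ap`, `ml`, `stage`, `region`, `quality`,
#'   `lib_size`, `cycle` and per-gene `archetype`, `base_rate`, `mito`.
#' @export
simulate_tissue <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n_cells <- cfg$n_cells * cfg$n_stages
  stage <- rep(seq_len(cfg$n_stages) - 1L, each = cfg$n_cells)
  ap <- runif(n_cells)
  ml <- runif(n_cells, -1, 1)
  cyc <- runif(n_cells)
  lib <- rlnorm(n_cells, cfg$lib_mu, cfg$lib_sigma)
  region <- region_from_coords(ap, ml, cfg$midline_halfwidth)

  genes <- assign_archetypes(cfg)
  base <- rlnorm(nrow(genes), meanlog = 0, sdlog = 1)
  # named marker genes get neutral base rates: curated markers are chosen
  # for robust, comparable expression, and signature scores compare raw
  # means across genes
  base[genes$gene %in% c(unlist(region_marker_sets()),
                         ml_axis_markers()$lateral)] <- 1
  # mito housekeeping sized so the healthy mito fraction sits near 4%
  base[genes$mito] <- sum(base[!genes$mito]) * 0.04 /
    (0.96 * sum(genes$mito))
  genes$base_rate <- base
  genes$dispersion <- cfg$dispersion

  fmat <- matrix(1, n_cells, nrow(genes))
  for (g in seq_len(nrow(genes))) {
    if (genes$archetype[g] == "null" || genes$archetype[g] == "stress") next
    fmat[, g] <- archetype_factor(genes$archetype[g], genes$param[[g]],
                                  ap, ml, stage, cyc, cfg$amplitude,
                                  cfg$n_stages)
  }
  w <- sweep(fmat, 2, base, "*")
  mu <- w * (lib / rowSums(w))
  counts <- matrix(rnbinom(length(mu), size = cfg$dispersion, mu = mu),
                   n_cells, nrow(genes))
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)), genes$gene)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  cells <- data.frame(cell = rownames(counts), ap = ap, ml = ml,
                      stage = stage, region = region, quality = "high",
                      lib_size = lib, cycle = cyc, stringsAsFactors = FALSE)
  truth <- list(cells = cells, genes = genes, config = cfg)
  out <- list(counts = counts, truth = truth)
  if (cfg$lowq_frac > 0)
    out <- inject_low_quality_cells(out$counts, out$truth, cfg$lowq_frac,
                                    seed = cfg$seed + 1L)
  out
}

#' Expected mean matrix implied by the simulator truth
#'
#' Reconstructs \eqn{\mu_{cg}} from the truth tables (high-quality state,
#' before any low-quality injection). Used by moment-matching oracles.
#'
#' @param truth the `truth` element returned by [simulate_tissue()].
#' @return dense cells x genes matrix of negative-binomial means.
#' @export
expected_mean_matrix <- function(truth) {
  cfg <- truth$config
  cells <- truth$cells
  genes <- truth$genes
  fmat <- matrix(1, nrow(cells), nrow(genes))
  for (g in seq_len(nrow(genes))) {
    if (genes$archetype[g] %in% c("null", "stress")) next
    fmat[, g] <- archetype_factor(genes$archetype[g], genes$param[[g]],
                                  cells$ap, cells$ml, cells$stage,
                                  cells$cycle, cfg$amplitude, cfg$n_stages)
  }
  w <- sweep(fmat, 2, genes$base_rate, "*")
  mu <- w * (cells$lib_size / rowSums(w))
  dimnames(mu) <- list(cells$cell, genes$gene)
  mu
}

#' Inject a low-quality cell mode
#'
#' Converts a fixed fraction of cells to a low-quality state: the library
#' is binomially thinned by a factor drawn from `[0.05, 0.2]`, the
#' mitochondrial fraction is inflated above 20% (target drawn from
#' `[0.25, 0.5]`) and counts are added on the stress program genes.
#'
#' @param counts sparse cells x genes count matrix.
#' @param truth matching truth list from [simulate_tissue()].
#' @param lowq_frac fraction of cells converted; `round(lowq_frac * n)`
#'   cells are selected.
#' @param seed integer seed.
#' @return list with updated `counts` and `truth` (`quality` column set).
#' @export
inject_low_quality_cells <- function(counts, truth, lowq_frac, seed = 1L) {
  if (lowq_frac < 0 || lowq_frac >= 1) stopf("lowq_frac must lie in [0, 1)")
  if (lowq_frac == 0) return(list(counts = counts, truth = truth))
  set.seed(seed)
  n <- nrow(counts)
  n_low <- round(lowq_frac * n)
  pick <- sample.int(n, n_low)
  dense <- as_dense(counts)
  mito <- which(truth$genes$mito)
  stress <- which(truth$genes$archetype == "stress")
  for (ci in pick) {
    x <- dense[ci, ]
    keep <- runif(1, 0.05, 0.2)
    x <- rbinom(length(x), size = as.integer(x), prob = keep)
    tot <- sum(x)
    if (tot == 0) { x[mito[1]] <- 1; tot <- 1 }
    # stress program burst: ~30% of the remaining library on stress genes
    if (length(stress)) {
      extra <- stats::rmultinom(1, size = max(1, round(0.3 * tot)),
                                prob = rep(1, length(stress)))[, 1]
      x[stress] <- x[stress] + extra
      tot <- sum(x)
    }
    target_mf <- runif(1, 0.25, 0.5)
    m_now <- sum(x[mito])
    add <- max(0, round((target_mf * tot - m_now) / (1 - target_mf)))
    if (add > 0) {
      extra <- stats::rmultinom(1, size = add, prob = rep(1, length(mito)))[, 1]
      x[mito] <- x[mito] + extra
    }
    dense[ci, ] <- x
  }
  truth$cells$quality[pick] <- "low"
  counts <- methods::as(methods::as(Matrix::Matrix(dense, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  list(counts = counts, truth = truth)
}

#' Simulate two cell groups with planted fold-changes
#'
#' Negative-binomial counts for a control and a perturbed group sharing
#' base rates and log-normal library sizes; a chosen fraction of genes
#' carries a multiplicative fold-change in the perturbed group. Used to
#' calibrate the hurdle differential-expression test (null when
#' `fold = 1` or `frac_de = 0`).
#'
#' @param n_cells cells per group.
#' @param n_genes genes.
#' @param frac_de fraction of genes perturbed.
#' @param fold fold-change applied to perturbed genes in group B.
#' @param dispersion NB size parameter.
#' @param lib_mu,lib_sigma log-normal library parameters.
#' @param seed integer seed.
#' @return list with `counts_a`, `counts_b` (dense cells x genes),
#'   `de_genes` (indices perturbed).
#' @export
simulate_two_groups <- function(n_cells = 300, n_genes = 1000,
                                frac_de = 0.1, fold = 1.5, dispersion = 2,
                                lib_mu = log(16000), lib_sigma = 0.3,
                                seed = 0) {
  set.seed(seed)
  base <- rlnorm(n_genes, 0, 1)
  de_genes <- if (frac_de > 0) sample.int(n_genes, round(frac_de * n_genes))
    else integer(0)
  f_b <- rep(1, n_genes)
  f_b[de_genes] <- fold
  draw <- function(fvec) {
    lib <- rlnorm(n_cells, lib_mu, lib_sigma)
    w <- outer(rep(1, n_cells), base * fvec)
    mu <- w * (lib / rowSums(w))
    m <- matrix(rnbinom(length(mu), size = dispersion, mu = mu),
                n_cells, n_genes)
    colnames(m) <- sprintf("gene%04d", seq_len(n_genes))
    m
  }
  list(counts_a = draw(rep(1, n_genes)), counts_b = draw(f_b),
       de_genes = de_genes)
}
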