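#!/usr/bin/env Rscript
# Generate the two synthetic study datasets: the six-stage patterned
# atlas (3000 cells x 2000 genes, amplitude 4) and a quality-control
# fixture with a 20% injected low-quality mode. Writes MTX fixtures with
# complete ground truth under results/data/.

library(cnpaxes)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

atlas <- simulate_tissue(sim_config(seed = 0))
write_fixture(atlas$counts, atlas$truth, "results/data/atlas")
message(sprintf("atlas: %d cells x %d genes, median library %d UMIs",
                nrow(atlas$counts), ncol(atlas$counts),
                round(median(Matrix::rowSums(atlas$counts)))))
print(table(archetype = atlas$truth$genes$archetype))
print(table(region = atlas$truth$cells$region))

qc_fix <- simulate_tissue(sim_config(n_cells = 200, n_genes = 800,
                                     lowq_frac = 0.2, seed = 11))
write_fixture(qc_fix$counts, qc_fix$truth, "results/data/qc_fixture")
message(sprintf("qc fixture: %d cells, %d flagged low-quality",
                nrow(qc_fix$counts),
                sum(qc_fix$truth$cells$quality == "low")))
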