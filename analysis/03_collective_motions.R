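#!/usr/bin/env Rscript
# Stage 3: the correlation / collective-motion layer -- DCCM, Calpha PCA,
# the free-energy surface over (PC1, PC2), and per-residue displacement
# along PC1.  Run analysis/01_generate_ensembles.R first.

suppressMessages(library(esterdyn))

dir.create("results", showWarnings = FALSE)

for (role in c("wt", "mut")) {
  ens <- read_ensemble("scratch/demo/topology.pdb",
                       sprintf("scratch/demo/%s.dcd", role))
  ca <- select_atoms(ens$topology, "ca")
  cm <- dccm(ens, ca)
  write.table(format(unclass(cm), digits = 4),
              sprintf("results/03_%s_dccm.tsv", role), sep = "\t",
              quote = FALSE)
  pc <- pca_ensemble(ens, ca, n_components = 2)
  fes <- fes_2d(pc$projections, n_bins = 60)
  grid <- expand.grid(pc1 = fes$xmids, pc2 = fes$ymids)
  grid$free_energy <- as.vector(fes$energy)
  write.table(grid[!is.na(grid$free_energy), ],
              sprintf("results/03_%s_fes.tsv", role), sep = "\t",
              quote = FALSE, row.names = FALSE)
  disp <- mode_displacement_map(pc, 1)
  write.table(disp, sprintf("results/03_%s_pc1_displacement.tsv", role),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lid <- disp$resno %in% 182:199
  tot <- sum(pc$values)
  cat(sprintf(
    "%s: PC1 %.0f%% / PC2 %.0f%% of variance; lid share of PC1 %.0f%%; FES minimum at (%.1f, %.1f)\n",
    role, 100 * pc$values[1] / tot, 100 * pc$values[2] / tot,
    100 * sum(disp$displacement[lid]^2) / sum(disp$displacement^2),
    fes_minimum(fes)["x"], fes_minimum(fes)["y"]))
}
cat("\nIn the mutant PC1 is the planted lid-opening mode (the lid carries\n")
cat("nearly all of it) and the FES is bimodal along PC1.  In the wild type\n")
cat("the soft subdomain motions dominate PC1 and the lid mode mixes into\n")
cat("lower components -- the two roles sample along different collective\n")
cat("coordinates.\n")
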