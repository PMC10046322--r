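#!/usr/bin/env Rscript
# Stage 2: first-line stability statistics per role -- Calpha RMSD series,
# per-residue RMSF about the iterative average structure, radius of
# gyration, and two-cluster populations from all-pairs best-fit RMSD.
# Run analysis/01_generate_ensembles.R first.

suppressMessages(library(esterdyn))

dir.create("results", showWarnings = FALSE)
summary_rows <- list()
profiles <- list()

for (role in c("wt", "mut")) {
  ens <- read_ensemble("scratch/demo/topology.pdb",
                       sprintf("scratch/demo/%s.dcd", role))
  ca <- select_atoms(ens$topology, "ca")
  rmsd <- rmsd_series(ens, fit_mask = ca)
  prof <- rmsf_profile(ens, ca)
  rg <- radius_of_gyration(ens, ca)
  cl <- cluster_frames(ens, ca, k = 2)
  profiles[[role]] <- prof
  write.table(data.frame(frame = seq_along(rmsd), rmsd = rmsd, rg = rg,
                         cluster = cl$labels),
              sprintf("results/02_%s_frames.tsv", role), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lid <- prof$resno %in% 182:199
  summary_rows[[role]] <- data.frame(
    role = role, mean_rmsd = mean(rmsd), mean_rg = mean(rg),
    lid_rmsf = mean(prof$rmsf[lid]), nonlid_rmsf = mean(prof$rmsf[!lid]),
    cluster1_fraction = cl$fractions[1], cluster2_fraction = cl$fractions[2])
}

delta <- rmsf_difference(profiles$mut, profiles$wt)
write.table(data.frame(resno = profiles$wt$resno, wt = profiles$wt$rmsf,
                       mut = profiles$mut$rmsf, delta = delta$delta),
            "results/02_rmsf_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tab <- do.call(rbind, summary_rows)
write.table(tab, "results/02_stability_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Stability summary (lid = residues 182-199):\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nLid RMSF is %.2f A higher in the mutant role.  In the mutant
the two-cluster split recovers the planted open/closed lid populations
(~2/3 vs 1/3); in the wild type the loosely coupled subdomains dominate
the pairwise-RMSD landscape, so its lid states do not separate into
clusters -- the lid trace (stage 5) resolves them instead.\n",
            tab$lid_rmsf[tab$role == "mut"] -
              tab$lid_rmsf[tab$role == "wt"]))
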