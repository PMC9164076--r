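#!/usr/bin/env Rscript
# Docking-score triage of the hub-target ligands.
#
# Emits the grid-box configuration used for the docking runs, parses the
# reference eight-ligand score table, and classifies binders at the
# -6.0 kcal/mol activity threshold.

library(netpharm)

dir.create("results", showWarnings = FALSE)

box <- grid_box(center = c(128.688, 128.088, 133.365), size = c(40, 40, 40))
writeLines(make_grid_config(box, "receptor.pdbqt", "ligand.pdbqt"),
           "results/vina_config.txt", sep = "")

rec <- parse_scores(system.file("extdata", "grin2b_docking.tsv",
                                package = "netpharm"))
tri <- classify_binders(rec, threshold = -6.0)
flat <- tri$records
flat$hbond_residues <- vapply(flat$hbond_residues, paste, "", collapse = ",")
flat$hydrophobic_residues <- vapply(flat$hydrophobic_residues, paste, "",
                                    collapse = ",")
write.table(flat, "results/triage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Parsed %d docking records against %s.\n", nrow(rec),
            rec$receptor[1]))
cat(sprintf("Actives (< %.1f kcal/mol): %d; inactives: %d (%s)\n",
            tri$threshold, tri$n_active, tri$n_inactive,
            paste(tri$records$ligand[!tri$records$active], collapse = ", ")))
best <- best_binder(rec)
cat(sprintf("Best binder: %s at %.1f kcal/mol\n",
            best$ligand, best$binding_energy))
cat("Wrote results/vina_config.txt and results/triage.tsv\n")
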