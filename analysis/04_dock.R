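#!/usr/bin/env Rscript

# Stage 4: docking validation of the screened candidates.
#
# Prepares a receptor, docks each passing candidate into the study's grid
# box (80 x 60 x 60 points at 0.375 A centered at 23.895/49.094/134.275,
# 20 poses) and reports the best energy plus hydrogen-bond contacts of
# the top pose.  Offline, the stage runs against the packaged toy
# receptor with the mock engine adapter; pointing `receptor` at a real
# estrogen-receptor PDB and `engine` at a QuickVina 2 / AutoDock binary
# runs the same code against the real target.

suppressMessages(library(leadopt))

passing_path <- "results/screen/passing.csv"
if (!file.exists(passing_path))
  stop("run analysis/03_screen.R first (missing ", passing_path, ")")
passing <- read.csv(passing_path, stringsAsFactors = FALSE)

cands <- passing$smiles
if (!length(cands)) {
  cat("no candidates passed screening; docking the lead instead\n")
  cands <- to_canonical_smiles(lead_structure())
} else if (length(cands) > 5L) {
  ord <- order(passing$affinity_kcal_mol)
  cands <- passing$smiles[ord][1:5]
}

box <- build_grid_box(c(80L, 60L, 60L), 0.375,
                      c(23.895, 49.094, 134.275))
res <- run_dock(cands, toy_receptor(), box = box,
                engine = engine_config("mock"), poses = 20L,
                out_dir = "results/dock")

cat("docked", nrow(res$energies), "candidate(s), 20 poses each\n")
for (i in seq_len(nrow(res$energies)))
  cat(sprintf("  %s  best %.2f kcal/mol\n", res$energies$smiles[i],
              res$energies$best_kcal_mol[i]))
if (nrow(res$contacts)) {
  cat("hydrogen-bond contacts of best poses:\n")
  print(res$contacts[, c("smiles", "donor_owner", "donor_label",
                         "residue", "distance", "class")])
} else {
  cat("no hydrogen-bond contacts within 3.5 A for the mock poses\n")
}
cat("wrote results/dock/\n")
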