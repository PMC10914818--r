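#!/usr/bin/env Rscript

# Stage 3: screen the optimized episode log.
#
# Applies the selection thresholds (SA >= 0.6, QED >= 0.7, affinity
# <= -10 kcal/mol, inclusive), reports what fraction of episodes beats
# each threshold individually, the reward-density modes, and the
# episode-index trends that show the epsilon-greedy decay steering the
# search.

suppressMessages(library(leadopt))

log_path <- "results/optimize/episodes.csv"
if (!file.exists(log_path))
  stop("run analysis/02_optimize.R first (missing ", log_path, ")")

rep <- run_screen(log_path, screening_thresholds(),
                  out_dir = "results/screen")

fr <- rep$fractions$inclusive
cat(sprintf("fractions beating each threshold: SA %.1f%%, QED %.1f%%, affinity %.1f%%\n",
            100 * fr$sa, 100 * fr$qed, 100 * fr$affinity))
cat(sprintf("density modes: affinity %.2f kcal/mol, QED %.2f, SA %.2f\n",
            rep$densities$affinity$modes[1], rep$densities$qed$modes[1],
            rep$densities$sa$modes[1]))
cat(sprintf("trends vs episode: affinity rho %.2f (p %.2g), QED rho %.2f, SA rho %.2f\n",
            rep$trends$affinity$rho, rep$trends$affinity$p_value,
            rep$trends$qed$rho, rep$trends$sa$rho))
cat(nrow(rep$passing), "unique candidate(s) pass all three thresholds\n")
if (nrow(rep$passing)) {
  best <- utils::head(rep$passing[order(rep$passing$affinity_kcal_mol), ],
                      3L)
  for (i in seq_len(nrow(best)))
    cat(sprintf("  %s  (affinity %.2f, QED %.2f, SA %.2f)\n",
                best$smiles[i], best$affinity_kcal_mol[i], best$qed[i],
                best$sa[i]))
}
cat("wrote results/screen/\n")
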