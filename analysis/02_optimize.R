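#!/usr/bin/env Rscript

# Stage 2: reinforcement-learning optimization from the lead.
#
# Runs the smoke-scale study conditions (200 episodes of at most 8 edits,
# epsilon decaying linearly from 1 by 1/episodes, deterministic surrogate
# affinity in place of the docking engine) and, for contrast, the same
# episode budget with a pure-random agent.  The study-scale conditions
# (6000 episodes, 16 edits, docking affinity in the loop) use the same
# entry point with `agent_config()` defaults and a docking-adapter reward
# and are not run here.

suppressMessages(library(leadopt))

cfg <- seeded_smoke_config()

cat("optimizing:", cfg$agent$episodes, "episodes, step limit",
    cfg$mdp$step_limit, ", master seed", cfg$agent$seed, "\n")
log <- run_optimize(cfg, out_dir = "results/optimize", agent = "dqn")
cat("wrote results/optimize/episodes.csv (", nrow(log), "episodes )\n")

rand <- run_optimize(cfg, out_dir = "results/optimize_random",
                     agent = "random")

wt <- wilcox.test(log$scalar_reward, rand$scalar_reward,
                  alternative = "greater", exact = FALSE)
cat(sprintf("mean scalar reward: trained %.3f vs random %.3f (Mann-Whitney p = %.2g)\n",
            mean(log$scalar_reward), mean(rand$scalar_reward),
            wt$p.value))
cat(sprintf("best episode: %s (affinity %.2f kcal/mol, QED %.2f, SA %.2f)\n",
            log$smiles[which.max(log$scalar_reward)],
            log$affinity_kcal_mol[which.max(log$scalar_reward)],
            log$qed[which.max(log$scalar_reward)],
            log$sa[which.max(log$scalar_reward)]))
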