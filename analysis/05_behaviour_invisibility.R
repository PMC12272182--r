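#!/usr/bin/env Rscript

# The behavioural invisibility test: simulated AXB discrimination blocks
# at chance accuracy are analyzed with the hierarchical Bayesian logistic
# regression; Savage-Dickey BF01 quantifies the evidence that observers
# cannot tell tagged from untagged stimuli. A simulation-based sensitivity
# analysis maps BF01 against true underlying accuracy: the null evidence
# peaks at chance and turns into evidence against the null away from it.

library(rifttag)

cfg <- default_config(seed = 20260920)
report <- suppressWarnings(run_demo(cfg, out_dir = "results", sections = 4))
beh <- report$behaviour

cat("Bayes factors for the simulated discrimination blocks (chance truth):\n")
print(beh$bf, row.names = FALSE, digits = 3)
cat("\nSensitivity curve (median BF01 by true accuracy):\n")
print(beh$sensitivity$levels, row.names = FALSE, digits = 3)
obs <- min(beh$bf$bf01)
rng <- beh$sensitivity$lookup(obs)
cat(sprintf("\nSmallest observed BF01 = %.2f corresponds to true accuracy in [%.2f, %.2f]\n",
            obs, rng[1], rng[2]))
cat("Tables written to results/behaviour_bf.csv and results/sensitivity_curve.csv\n")
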