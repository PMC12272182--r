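#!/usr/bin/env Rscript

# The fixed/random tagging-phase by ITC/phase-corrected-coherence contrast:
# inter-trial coherence requires a constant stimulation phase and collapses
# to the noise floor when the phase is randomized per trial, while
# brain-to-tagging coherence (which corrects each trial by the actually
# displayed tagging phase) keeps its SNR in both regimes.

library(rifttag)

cfg <- default_config(seed = 20260920)
report <- suppressWarnings(run_demo(cfg, out_dir = "results", sections = 2))

cat("Tagging SNR (dB at 60 Hz) by phase regime and analysis method:\n")
print(report$phase_2x2, row.names = FALSE, digits = 3)
cat("\nITC collapses for the random-phase block; the phase-corrected\n",
    "coherence keeps a strong tagging readout in both blocks\n",
    "(written to results/phase_2x2_snr.csv).\n")
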