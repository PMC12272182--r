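#!/usr/bin/env Rscript

# Orthogonal-phase tagging of two simultaneous stimuli: per simulated
# participant, the tagging-to-brain phase lag is estimated from an
# independent single-stimulus random-phase run, the two-stimulus data are
# projected at that lag and at the 90-degree-shifted lag, and an
# equivalent current dipole is fitted to each projected topography. With
# contralateral visual projection, the left-stimulus dipole should land in
# the right hemisphere (x > 0) and vice versa.

library(rifttag)

cfg <- default_config(seed = 20260920)
report <- suppressWarnings(run_demo(cfg, out_dir = "results", sections = 3))
pt <- report$phase_tagging

cat("Per-participant phase-tagging dipole fits:\n")
print(pt$table, row.names = FALSE, digits = 3)
cat(sprintf("\nContralateral rate: %.0f%%  |  mean dx = %.1f mm (sd %.1f)\n",
            100 * pt$contralateral_rate, pt$dx$summary["mean"],
            pt$dx$summary["sd"]))
cat(sprintf("Hierarchical contrast on x: BF10 = %.3g\n", pt$dx_bf10))
cat("KDE difference volume written to results/dipole_kde_diff.csv\n")
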