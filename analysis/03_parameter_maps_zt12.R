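#!/usr/bin/env Rscript
# Ictal and ictal-postictal parameter-space maps at the ZT12 transition
# state (8 x 8 grid; the full-protocol resolution is 40 x 40 and uses the
# same code path).
#
# The ictal map sweeps S_i (20-220%) against P_i (-20-40%); the transition
# from rhythmic to irregular to no firing runs along the sympathetic axis.
# The joint map sweeps S_i against P_p (60-400%) with P_i = 10% and
# S_p = -100%; the postictal transition runs along the parasympathetic
# axis, and crossing the two label sets yields the nine regions.

suppressMessages(library(sancpace))

res <- run_experiment(list(experiment = "fig_maps",
                           context = list(zt = 12, vigilance = "natural"),
                           grid = list(n_per_axis = 8),
                           out_dir = "results/maps_zt12"),
                      quiet = FALSE)
cat("ictal-phase pattern fractions:\n"); print(round(res$ictal_areas, 3))
cat("postictal-phase pattern fractions:\n")
print(round(res$postictal_areas, 3))
cat("\nMaps (fr.csv, labels, regions, meta.json) under results/maps_zt12/\n")
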