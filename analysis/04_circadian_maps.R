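#!/usr/bin/env Rscript
# Circadian and vigilance-state dependence of the seizure-outcome maps.
#
# Reruns the ictal and joint sweeps at natural sleep (ZT6), natural
# wakefulness (ZT18) and the two decoupled vigilance states, then compares
# the no-firing fractions: wakefulness (natural or forced) expands the
# ictal no-firing region, sleep (natural or forced) expands the postictal
# one -- the vigilance state, not clock time per se, carries the postictal
# risk.

suppressMessages(library(sancpace))
dir.create("results/circadian_maps", showWarnings = FALSE, recursive = TRUE)

params <- build_default_params()
combos <- list(
  c("ictal", 18, "natural"),      c("ictal", 6, "natural"),
  c("ictal", 6, "forced_awake"),
  c("postictal", 6, "natural"),   c("postictal", 18, "natural"),
  c("postictal", 18, "forced_sleep"))

rows <- list()
for (k in combos) {
  key <- paste(k, collapse = "_")
  m <- run_map(build_grid(k[1], 8),
               circadian_context(as.numeric(k[2]), k[3]), params)
  write_map(m, file.path("results/circadian_maps", key))
  a <- region_areas(m, k[1])
  rows[[key]] <- data.frame(map = k[1], zt = as.numeric(k[2]),
                            vigilance = k[3], frac_R = a["R"],
                            frac_I = a["I"], frac_N = a["N"])
  cat(sprintf("%-28s R %.3f I %.3f N %.3f\n", key, a["R"], a["I"], a["N"]))
}
tab <- do.call(rbind, rows)
data.table::fwrite(tab, "results/circadian_maps/summary.csv")

nf <- function(map, zt, vig) tab$frac_N[tab$map == map & tab$zt == zt &
                                          tab$vigilance == vig]
cat(sprintf("\nictal no-firing:   awake %.3f / forced awake %.3f > sleep %.3f\n",
            nf("ictal", 18, "natural"), nf("ictal", 6, "forced_awake"),
            nf("ictal", 6, "natural")))
cat(sprintf("postictal no-firing: sleep %.3f / forced sleep %.3f > awake %.3f\n",
            nf("postictal", 6, "natural"), nf("postictal", 18, "forced_sleep"),
            nf("postictal", 18, "natural")))
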