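#!/usr/bin/env Rscript
# Food-output and economic consequences of the three strategies at
# their sweep endpoints: per-year output deltas, one-sided leakage
# (imports) and the discounted opportunity cost of forgone production.

suppressMessages(library(sparesim))

L <- read_landscape("results/landscape")
endpoint <- list(
  sharing = policy_spec("sharing", "equal", "grassland",
                        0.15 * total_farmland(L)),
  sparing = policy_spec("sparing", "cost_min", "grassland", 0.05),
  sparing3c = policy_spec("sparing3c", "cost_min", "grassland", 0.05))

rows <- lapply(names(endpoint), function(nm) {
  o <- run_scenario(L, endpoint[[nm]])
  data.frame(strategy = nm,
             spared_area_ha = o$spared_area_ha,
             delta_food_year1 = o$delta_food$delta[1],
             delta_food_npv = o$delta_food_npv,
             leakage_npv = o$leakage_npv,
             opportunity_cost_npv = o$opportunity_cost_npv,
             gain_in_occupancy = o$gain_in_occupancy)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/economics_summary.csv", row.names = FALSE)

cat("strategy endpoints (grassland):\n")
print(tab, row.names = FALSE, digits = 6)
cat("\nSharing removes output (leakage NPV > 0); Sparing is output-\n")
cat("neutral every year; Three-Compartment Sparing yields a small\n")
cat("surplus, so neither sparing variant induces import leakage.\n")
cat("written to results/economics_summary.csv\n")
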