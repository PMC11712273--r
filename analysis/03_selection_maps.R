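#!/usr/bin/env Rscript
# Spatial selection maps: where does each allocation rule place
# conservation land?  Exports ESRI ASCII rasters and CSVs for the two
# contrasting rules (cost minimization under Sparing at the 5% uplift;
# biodiversity maximization under Sharing at the 15%-of-farmland
# target), plus the richness-change map of the cost-min run.

suppressMessages(library(sparesim))

L <- read_landscape("results/landscape")
dir.create("results/maps", recursive = TRUE, showWarnings = FALSE)
up <- L$cells$stratum == "upland"

cm <- run_scenario(L, policy_spec("sparing", "cost_min", "grassland", 0.05))
write_map(cm$selection_map, L, "results/maps/sparing_costmin_selection.asc")
write_map(cm$selection_map, L, "results/maps/sparing_costmin_selection.csv",
          "csv")
write_map(cm$richness_map, L, "results/maps/sparing_costmin_richness.asc")
conv <- cm$allocation$cells$habitat_ha + cm$allocation$cells$lowyield_ha
cat(sprintf("cost_min sparing 5%%: %.0f ha spared, upland share %.3f\n",
            cm$spared_area_ha, sum(conv[up]) / cm$spared_area_ha))

target <- 0.15 * total_farmland(L)
bm <- run_scenario(L, policy_spec("sharing", "biodiv_max", "grassland",
                                  target))
write_map(bm$selection_map, L, "results/maps/sharing_biodivmax_selection.asc")
write_map(bm$selection_map, L, "results/maps/sharing_biodivmax_selection.csv",
          "csv")
conv <- bm$allocation$cells$habitat_ha
cat(sprintf("biodiv_max sharing 15%%: %.0f ha, upland share %.3f (upland farmland share %.3f)\n",
            bm$spared_area_ha, sum(conv[up]) / bm$spared_area_ha,
            sum(L$cells$farmland_area[up]) / total_farmland(L)))
cat("maps written to results/maps/\n")
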