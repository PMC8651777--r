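#!/usr/bin/env Rscript

# Step 3: cross-state and cross-pollutant summary.
#
# Tabulates the per-state effects against the known ground truth, computes
# the cross-pollutant ratio rho = delta_NO2 / delta_PM2.5 (negative when
# the pollutants moved in opposite directions), and checks model adequacy
# (MASE < 1 against the one-step naive benchmark in every state).

suppressPackageStartupMessages(library(bagsarima))

effects <- read.csv("results/effects.csv")
truth <- read.csv("results/truth.csv")
assess <- read.csv("results/assessment.csv")

for (pol in unique(effects$pollutant)) {
  e <- effects[effects$pollutant == pol, ]
  tr <- if (pol == "no2") truth$delta_no2 else truth$delta_pm25
  tr <- tr[match(e$state, truth$state)]
  message(sprintf(
    "%s: delta range [%.2f, %.2f], mean %.2f; significant in %d of %d states; mean signed error vs truth %.2f",
    pol, min(e$delta), max(e$delta), mean(e$delta), sum(e$significant),
    nrow(e), mean(e$delta - tr)))
}

no2 <- effects[effects$pollutant == "no2", ]
pm <- effects[effects$pollutant == "pm25", ]
pm <- pm[match(no2$state, pm$state), ]
ratios <- do.call(rbind, lapply(seq_len(nrow(no2)), function(i) {
  r <- compute_ratio(no2$delta[i], pm$delta[i])
  data.frame(state = no2$state[i], rho = r$rho, defined = r$defined)
}))
message(sprintf("rho < 0 (opposite-direction changes) in %d of %d states",
                sum(ratios$rho < 0, na.rm = TRUE), nrow(ratios)))

message(sprintf("MASE < 1 in %d of %d state-series (max %.2f)",
                sum(assess$mase < 1), nrow(assess), max(assess$mase)))

write.csv(ratios, "results/ratios.csv", row.names = FALSE)
message("wrote results/ratios.csv")
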