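#!/usr/bin/env Rscript
# Stage 6: mechanistic cross-check with the soil-water-balance simulator.
#
# Runs paired control / nonpriming / priming weather scenarios through the
# simulator, reports the yield and root-depth ordering the priming
# hypothesis predicts, and repeats the comparison with the root-deepening
# mechanism disabled to show the signal vanishes.

library(primecrop)

params <- crop_params("maize")
config <- simulation_config(seed = 42, n_counties = 10, years = 2000:2018)
scenarios <- cropsim_scenarios(config, params, n_draws = 100)

ex <- priming_experiment(params, scenarios)
cat("with the root-deepening mechanism:\n")
print(ex$summary, row.names = FALSE)
cat(sprintf("yield ordering control >= priming >= nonpriming: %s\n",
            ex$yield_ordering_holds))
cat(sprintf("priming root depth exceeds control: %s\n",
            ex$root_depth_ordering_holds))

ablated <- crop_params("maize", stress_root_boost = 1)
ex0 <- priming_experiment(ablated, scenarios)
cat("\nmechanism disabled (stress_root_boost = 1):\n")
print(ex0$summary, row.names = FALSE)
gap <- ex0$summary$mean_yield[ex0$summary$scenario == "priming"] -
  ex0$summary$mean_yield[ex0$summary$scenario == "nonpriming"]
cat(sprintf("priming - nonpriming gap without the mechanism: %.3f Mg/Ha\n",
            gap))

write.csv(rbind(cbind(ex$summary, mechanism = "on"),
                cbind(ex0$summary, mechanism = "off")),
          "results/cropsim_summary.csv", row.names = FALSE)
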