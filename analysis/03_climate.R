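#!/usr/bin/env Rscript
# Stage 3: aggregate daily weather over the detected phenological durations
# and classify drought/heat exposure (drought index bins, standardized
# precipitation and temperature anomalies).

library(primecrop)

weather <- read.csv("results/synthetic/weather.csv")
phenology <- read.csv("results/phenology.csv")

climate <- climate_table(weather, phenology)
write.csv(climate, "results/duration_climate.csv", row.names = FALSE)

cat("drought-index class distribution by duration:\n")
print(table(climate$duration, climate$pdsi_class))
cat("\nstandardized precipitation anomaly classes:\n")
print(table(climate$duration, climate$spa_class))
cat(sprintf("\nwrote %d duration-climate rows\n", nrow(climate)))
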