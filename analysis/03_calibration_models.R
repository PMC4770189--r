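#!/usr/bin/env Rscript
# Stage 3: fit the organ dry-weight calibration models.
#
# Shoots: AIC-selected linear model over length, log(length), GDD and the
# log(length) x GDD interaction, fitted on fruited-tree samples only (its
# predictions are lower bounds for defruited shoots). Fruits: AIC-selected
# model over log spheroid volume, GDD and treatment, under a Gamma
# log-link so predictions stay positive over the full seasonal mass range.

suppressPackageStartupMessages(library(orchardgrowth))

calib <- utils::read.csv("results/data/calibration.csv")
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

shoot <- fit_dry_weight_model(
  calib[calib$organ_type == "shoot" & calib$treatment == "FRU", ],
  organ = "shoot", family = "gaussian")
fruit <- fit_dry_weight_model(
  calib[calib$organ_type == "fruit", ], organ = "fruit", family = "gamma")

write_allometric_model(shoot, "results/models/shoot_dry_weight.json")
write_allometric_model(fruit, "results/models/fruit_dry_weight.json")

print(shoot)
print(fruit)
cat("\nwood allometry (fixed coefficients, not refitted):\n")
cat(sprintf("  biomass at unit trunk diameter: %.4f g\n", wood_agb(pi)))
cat(sprintf("  a 25 cm circumference trunk:    %.0f g\n", wood_agb(25)))
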