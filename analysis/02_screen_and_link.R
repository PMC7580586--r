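#!/usr/bin/env Rscript
# Stage 2: outlier screening and fur-soil transfer regressions.
#
# Screens profiles by squared robust Mahalanobis distance (MCD estimator,
# chi-square 0.975 cutoff on 14 df), then fits the per-element OLS of fur on
# soil concentration at each sample's cell. Writes the screened sample table,
# the outlier report and a per-element regression table.

library(elementscape)

profiles <- read_profile_table("results/data/fur_profiles.csv")
soil <- read_soil_grids("results/data/soil")

screen <- flag_outliers(profiles, quantile = 0.975)
clean <- drop_outliers(profiles, screen)
cat(sprintf("outlier screen: %d of %d flagged (cutoff chi2 = %.1f), %d retained\n",
            length(screen$flagged), nrow(profiles), screen$cutoff, nrow(clean)))
utils::write.csv(
  data.frame(sample_id = names(screen$distance),
             sq_mahalanobis = unname(screen$distance),
             flagged = names(screen$distance) %in% screen$flagged),
  "results/outlier_report.csv", row.names = FALSE)
write_profile_table(clean, "results/data/fur_profiles_screened.csv")

reg <- fit_element_regressions(clean, soil_at_locations(soil, clean))
utils::write.csv(as.data.frame(reg), "results/element_regressions.csv",
                 row.names = FALSE)
cat(sprintf("fur-soil coupling: R-squared %.3f-%.3f, %d element(s) with p < 0.05\n",
            min(reg$r_squared), max(reg$r_squared), sum(reg$p_value < 0.05)))
cat("weak per-element coupling means single elements cannot source individuals;\n")
cat("stage 3 summarizes the panel into spatially weighted components instead.\n")
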