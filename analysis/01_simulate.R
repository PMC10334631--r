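#!/usr/bin/env Rscript
# Step 1: generate the demo claims bundle.
#
# Simulates 2,618 colorectal cancer patients (the size of the motivating
# national-sample cohort) with a 60-drug panel: 56 null drugs plus four
# planted signals (two protective at HR 0.5, two detrimental at HR 2.0).
# Writes the raw claims tables, the scenario file and the ground truth to
# results/demo/.

suppressPackageStartupMessages(library(mwascreen))

out <- "results/demo"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- demo_scenario(seed = 20150101)
write_scenario_config(cfg, file.path(out, "scenario.yaml"))

sim <- simulate_bundle(cfg)
write_claims_bundle(sim$bundle, file.path(out, "bundle"),
                    anticancer_atc_prefixes = cfg$anticancer_atc_prefixes)
write_ground_truth(sim, out)
write.csv(sim$covariates, file.path(out, "covariates.csv"),
          row.names = FALSE, quote = FALSE)

gt <- sim$ground_truth$survival
cat(sprintf("simulated %d patients: %d deaths (%.0f%% of cohort), %.0f%% of deaths cancer-specific\n",
            nrow(gt), sum(gt$event_all_cause),
            100 * mean(gt$event_all_cause),
            100 * mean(gt$true_cause[gt$event_all_cause == 1] ==
                         "target_cancer")))
cat(sprintf("mean follow-up %.1f months; %d prescription rows over %d drugs\n",
            mean(gt$followup_days) / 30.44,
            nrow(sim$bundle$prescriptions), nrow(cfg$drugs)))
planted <- cfg$drugs[cfg$drugs$log_hr_all_cause != 0, ]
cat("planted signals:\n")
print(planted[, c("atc_code", "log_hr_all_cause")], row.names = FALSE)
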