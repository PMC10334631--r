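#!/usr/bin/env Rscript
# Step 3: classify per-drug exposure under the past-1-year incident-user
# design, at ATC levels 2 and 4, after excluding anticancer prescriptions.

suppressPackageStartupMessages(library(mwascreen))

out <- "results/demo"
bundle <- read_claims_bundle(file.path(out, "bundle"))
cohort <- read_cohort(file.path(out, "cohort.csv"))

for (level in c(2L, 4L)) {
  mat <- build_exposure_matrix(bundle, cohort, level, min_users = 1)
  long <- data.frame(patient_id = rep(rownames(mat), ncol(mat)),
                     drug = rep(colnames(mat), each = nrow(mat)),
                     class = as.vector(mat))
  path <- file.path(out, sprintf("exposure_L%d.csv", level))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  tab <- table(factor(mat, levels = exposure_class_levels()))
  cat(sprintf("ATC level %d: %d drugs; %d incident / %d prevalent / %d nonuser pairs\n",
              level, ncol(mat), tab[["incident_user"]],
              tab[["prevalent_user"]], tab[["nonuser"]]))
}
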