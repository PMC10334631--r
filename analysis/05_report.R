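#!/usr/bin/env Rscript
# Step 5: volcano tables and figures, validated-signal summary, manifest.

suppressPackageStartupMessages(library(mwascreen))

out <- "results/demo"
report <- readRDS(file.path(out, "screen_report.rds"))

files <- render_report(report, file.path(out, "report"))
cat("wrote", length(files), "files under", file.path(out, "report"), "\n")

sig <- report$validated_signals
if (nrow(sig)) {
  cat("validated signals:\n")
  print(sig[, c("drug", "level", "outcome", "hr", "direction")],
        row.names = FALSE)
} else {
  cat("no validated signals in this run\n")
}
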