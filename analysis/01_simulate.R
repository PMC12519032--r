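#!/usr/bin/env Rscript
# Generate the synthetic stand-in for the 1540 x 12 AML clinical table and
# write it (CSV + sidecar JSON schema) under results/.
suppressPackageStartupMessages(library(fedtabsim))

seed <- 1
dir.create("results", showWarnings = FALSE)
schema <- build_aml_schema()
fixture <- generate_fixture(schema, seed = seed)
write_clinical_table(fixture, "results/fixture.csv")

cat("fixture:", nrow(fixture$data), "records x", ncol(fixture$data), "columns\n")
cat("continuous:", paste(continuous_cols(schema), collapse = ", "), "\n")
cat("categorical:", paste(categorical_cols(schema), collapse = ", "), "\n")
cat("written to results/fixture.csv (+ .schema.json)\n")
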