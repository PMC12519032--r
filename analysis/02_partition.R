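#!/usr/bin/env Rscript
# Build the three federated data-distribution scenarios for every study
# node count and serialize the plans for traceability.
suppressPackageStartupMessages(library(fedtabsim))

fixture <- read_clinical_table("results/fixture.csv")
dir.create("results/partitions", showWarnings = FALSE)
for (N in c(3, 5, 7, 10)) {
  for (scenario in c("B", "IB", "IB_non_iid")) {
    plan <- make_partition(scenario, fixture, N, seed = derive_seed(1, scenario, N))
    path <- sprintf("results/partitions/%s_%dN.json", scenario, N)
    write_partition_plan(plan, path)
    cat(sprintf("%-10s N=%2d sizes: %s\n", scenario, N,
                paste(lengths(plan$assignments), collapse = " ")))
  }
}
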