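#!/usr/bin/env Rscript
# Generate the synthetic study population: 129 selfing diploid samples,
# 2,000 genes, rare + common SNPs/indels/SVs with planted cis-regulatory
# effects, and triplicate expression under wet and dry conditions.
source("analysis/00_common.R")

simulate_population(sim_config(seed = SIM_SEED), SIM_DIR)
truth <- read_tsv_df(file.path(SIM_DIR, "truth.tsv"))

summary_tab <- as.data.frame(table(truth$vclass, truth$category))
names(summary_tab) <- c("vclass", "category", "n")
write_tsv_df(summary_tab, file.path(RESULTS_DIR, "01_simulated_variants.tsv"))

message(sprintf("simulated %d variants (%d causal rare variants among %d rare)",
                nrow(truth), sum(truth$causal),
                sum(truth$category == "rare")))
message("wrote results/01_simulated_variants.tsv")
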