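# Shared setup for the analysis scripts: simulated study population location
# and output directory. Each numbered script is a thin driver over the
# rareburden package; run them in order from the repository root.
library(rareburden)

SIM_DIR <- "scratch/simdata"
RESULTS_DIR <- "results"
SIM_SEED <- 1L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

ensure_simulation <- function() {
  if (!file.exists(file.path(SIM_DIR, "variants.vcf"))) {
    message("simulating study population (seed ", SIM_SEED, ") ...")
    simulate_population(sim_config(seed = SIM_SEED), SIM_DIR)
  }
  invisible(SIM_DIR)
}
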