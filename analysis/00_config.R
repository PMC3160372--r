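# Shared configuration for the analysis scripts. Source()d by each numbered
# step so that every stage regenerates the same benchmark.

library(rcrnet)

SEED <- 42L
OUT_DIR <- "results/benchmark"

# Benchmark study conditions: 200 upstream controllers with 10 signed
# transcriptional targets each, 20 planted active (half up, half down),
# a 2.0 log2-unit expression shift against 0.5 log2-units of noise,
# 3 control vs 3 treated samples.
benchmark_config <- function(seed = SEED) {
  simulation_config(n_controllers = 200L, targets_per_controller = 10L,
                    n_planted = 20L, effect_size_delta = 2.0,
                    noise_sd = 0.5, replicates_per_group = 3L,
                    seed = seed)
}

dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)
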