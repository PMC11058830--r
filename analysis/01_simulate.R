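#!/usr/bin/env Rscript
# Generate the synthetic monthly lake system (temperature, precipitation,
# NDVI, lake level and area) with known seasonal harmonics, piecewise trends,
# lag/accumulation couplings and AR(1) noise, and write it with its ground
# truth under results/data/. Later scripts recover what is planted here.

library(hydroscale)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 20260901L

cfg <- synthetic_config(n_months = 240L, start = c(2001L, 1L), seed = seed)
system <- gen_coupled_system(cfg)
write_system(system, "results/data")

cat("Simulated", cfg$n_months, "months x", length(system$series),
    "variables (seed", seed, ") -> results/data/\n")
cat("Planted couplings for lake level:\n")
for (cp in cfg$couplings$level)
  cat(sprintf("  %-13s coef %+g, lag %d, accumulation %d months\n",
              cp$driver, cp$coefficient, cp$lag, cp$accumulation))
cat("Planted level trend: decline / stable / rise phases starting at months",
    paste(cfg$trends$level$breakpoints, collapse = ", "),
    "with slopes", paste(cfg$trends$level$slopes, collapse = ", "), "per month\n")
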