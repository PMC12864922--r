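#!/usr/bin/env Rscript

# Stage 7 -- RNA stability: simulate pulse-chase metabolic labeling reads
# (T>C conversions at 5% per T on labeled molecules; labeled fraction
# decays as 2^(-t/halflife)), count conversions per oligo at 0 h and
# 12 h, and form t12/t0 stability ratios per genotype plus their log2
# knockout/wild-type difference.

library(neuriteMPRA)

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "1"))
outdir <- "results/pipeline"
config <- default_config(seed = seed)

res <- stage_slam(config, outdir)
d <- res$delta$delta_stability
cat("oligos with defined delta stability:", sum(is.finite(d)), "\n")
cat("median delta stability:", round(median(d, na.rm = TRUE), 3), "\n")
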