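#!/usr/bin/env Rscript

# Stage 1 -- simulate every raw input of the study: the 3' UTR set with
# planted TDP-43 motifs (30 target / 60 background UTRs; occupied motifs
# accessible, the rest stem-buried), soma/neurite fractionation counts for
# wild-type and knockout cells (negative binomial, planted log2
# localization shift of 4 for targets), and CLIP-style peak/read
# intervals over the occupied motifs.
#
# Outputs land in results/pipeline/. Downstream stages read from there.

library(neuriteMPRA)

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "1"))
outdir <- "results/pipeline"
config <- default_config(seed = seed)

sim <- stage_simulate(config, outdir)

cat("UTRs simulated:", length(sim$utrs$utrs), "\n")
cat("planted motifs:", sum(sim$utrs$truth_motifs$planted),
    "(occupied:", sum(sim$utrs$truth_motifs$occupied), ")\n")
cat("CLIP peaks:", nrow(sim$clip$peaks),
    " reads:", nrow(sim$clip$reads), "\n")
cat("fractionation libraries:", ncol(sim$fractionation$counts), "\n")
cat("outputs in", outdir, "\n")
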