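#!/usr/bin/env Rscript

# Stage 3 -- design the tiling reporter pool over a 15-UTR subset
# (9 target + 6 background genes, mirroring the scale of a focused
# reporter experiment): filter UTR records (annotation tags, 10-kb cap,
# polyA conservation), merge isoforms into meta-UTRs, tile 260-nt oligos
# at 6-nt steps with 260-nt flank extension, and add a motif-mutated
# companion (GUGUG->CACAC etc.) plus 20-nt PCR handles for every
# motif-containing tile.

library(neuriteMPRA)

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "1"))
outdir <- "results/pipeline"
config <- default_config(seed = seed)

pool <- stage_design(config, outdir)
man <- pool$manifest
cat("pool oligos:", nrow(man),
    "(mutant companions:", sum(man$is_mutant), ")\n")
cat("motif-containing wild-type tiles:",
    sum(!man$is_mutant & man$motif_hits != ""), "\n")
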