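#!/usr/bin/env Rscript

# Stage 5 -- structural context of the motifs: fold each motif-containing
# wild-type oligo in 80-nt windows sliding by 10 nt, record per-position
# pairing probabilities (Boltzmann ensemble under the package's
# pair-counting model with helix cooperativity), and score each oligo by
# the mean pairing probability over its motif positions.

library(neuriteMPRA)

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "1"))
outdir <- "results/pipeline"
config <- default_config(seed = seed)

res <- stage_structure(config, outdir)
cat("oligos scored:", length(res$scores), "\n")
cat("score quartiles:",
    paste(round(quantile(res$scores), 3), collapse = " "), "\n")
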