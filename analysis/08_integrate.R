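#!/usr/bin/env Rscript

# Stage 8 -- integration: join localization, binding, stability and
# structure per oligo, classify oligos as no-motif / motif-without-CLIP /
# motif-with-CLIP, and run the headline Wilcoxon contrasts: the
# motif+CLIP class should be highest in delta LR, R and delta stability;
# mutant companions attenuated; and the accessible (bottom 20% pairing)
# motifs should carry the localization effect.

library(neuriteMPRA)

seed <- as.integer(Sys.getenv("PIPELINE_SEED", "1"))
outdir <- "results/pipeline"
config <- default_config(seed = seed)

res <- stage_integrate(config, outdir)
print(res$contrasts, row.names = FALSE)
cat("\nfull tables in", outdir, "\n")
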