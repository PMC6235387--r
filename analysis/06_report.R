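#!/usr/bin/env Rscript
# One-shot end-to-end run: the same prepare -> univariate -> sex-
# limitation -> pleiotropy sequence as scripts 01-05, orchestrated by
# run_pipeline() with stepwise covariate screening enabled, written as a
# complete report bundle (TSV tables + JSON mirror).

suppressPackageStartupMessages(library(thyrovc))

cfg <- pipeline_config(preset = "knhanes_total", seed = 20260101L,
                       covariate_set = "basic", stepwise = TRUE,
                       outdir = "results/report")
bundle <- run_pipeline(cfg)
print(bundle)
cat("\nfull report bundle written to results/report/\n")
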