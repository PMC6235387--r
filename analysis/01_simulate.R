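#!/usr/bin/env Rscript
# Generate the synthetic KNHANES-like family sample used by all later
# steps: ~1,115 households of 2-4 members with two correlated thyroid
# traits (TSH, fT4), sex, age, BMI, smoking, menopausal status, urinary
# iodine/creatinine and TPOAb.  Writes pedigree + phenotypes + truth to
# results/data/.

suppressPackageStartupMessages(library(thyrovc))
seed <- 20260101L

sc <- scenario_presets("knhanes_total")
sc$include_excludable <- TRUE   # leave some work for the exclusion cascade
d <- simulate_dataset(sc, seed)
write_dataset(d, "results/data")

cat(sprintf("simulated %d families, %d phenotyped individuals (%.1f%% male)\n",
            length(unique(d$phenotypes$fid)), nrow(d$phenotypes),
            100 * mean(d$phenotypes$sex == "male")))
cat(sprintf("median TSH %.2f mIU/L, median fT4 %.2f ng/dL\n",
            median(d$phenotypes$tsh), median(d$phenotypes$ft4)))
cat("written to results/data/ (pedigree.tsv, phenotypes.tsv, truth.json)\n")
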