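#!/usr/bin/env Rscript
# Simulate a small demonstration cohort and write it in the on-disk trial
# layout (TSV streams + RLE mask index per trial, cohort manifest).
# Larger cohorts are simulated on the fly by 03/04; this script exists to
# exercise and document the dataset format.

library(visuomotor)

out <- "results/dataset"
message("Simulating 2 intact subjects x 4 trials into ", out)
coh <- generate_cohort(2, 4, intact_profile(), desk_scene(), seed = 2026)
write_cohort(coh, out)

manifest <- read.table(file.path(out, "manifest.tsv"), header = TRUE,
                       sep = "\t", comment.char = "#")
print(manifest)
message(sprintf("%d trials written; planted schedules stored in meta.tsv",
                nrow(manifest)))
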