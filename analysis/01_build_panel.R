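#!/usr/bin/env Rscript
# Build the study panel: a synthetic 56-variant replicate-level dataset with
# the benchmark's planted discordance structure (23 pathogenic + 23 benign
# classified variants, 10 VUS), and write it in the tidy interchange format.
# Downstream scripts read this file, so the whole analysis is reproducible
# from one seed.

library(ybrca1)

seed <- 20220406L
panel <- generate_benchmark_panel(seed = seed)

dir.create("results", showWarnings = FALSE)
write_panel(panel, "results/panel.tsv")

cat("Panel:", nrow(panel$variants), "variants,",
    nrow(panel$measurements), "measurements ->", "results/panel.tsv\n")
print(table(panel$variants$prior_label))
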