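#!/usr/bin/env Rscript
# Differential H3K27ac binding at day 14: median-library normalized log2
# counts, per-region Welch t with a pooled-variance floor, and the joint
# FDR < 0.05 / |log2FC| > 1 call, for deprivation (E2D vs CTR) and
# re-stimulation (ReSt vs CTR) contrasts.

suppressMessages(library(estroepi))
outdir <- "results/run"

chip <- read_counts(file.path(outdir, "chip_counts.tsv"),
                    file.path(outdir, "chip_samples.tsv"), kind = "chip")
db <- call_differential_binding(chip, c("E2D", "CTR"))
write_result_table(db, file.path(outdir, "db.tsv"))
called <- db[db$called, ]
cat(sprintf("%d DB regions (E2D vs CTR): %d losses (%.1f%%), %d gains\n",
            nrow(called), sum(called$direction == "loss"),
            100 * mean(called$direction == "loss"),
            sum(called$direction == "gain")))

db_rest <- call_differential_binding(chip, c("ReSt", "CTR"))
write_result_table(db_rest, file.path(outdir, "db_rest.tsv"))
cat(sprintf("%d DB regions remain vs CTR after re-stimulation\n",
            sum(db_rest$called)))
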