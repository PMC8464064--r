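#!/usr/bin/env Rscript
# Differential expression: CPM filter (> 10 CPM in >= 2 samples), NB Wald
# GLM adjusting for timepoint, joint FDR < 0.05 / |log2FC| > 1 call, for
# deprivation and re-stimulation contrasts.

suppressMessages(library(estroepi))
outdir <- "results/run"

rna <- read_counts(file.path(outdir, "rna_counts.tsv"),
                   file.path(outdir, "rna_samples.tsv"), kind = "rna")
filtered <- filter_low_expression(rna, cpm_min = 10, min_samples = 2)
dropped <- attr(filtered, "filtered_out")
write_result_table(
  data.frame(unit_id = dropped,
             reason = rep("low_expression", length(dropped))),
  file.path(outdir, "rna_filter_audit.tsv"))
cat(sprintf("%d of %d genes pass the expression filter\n",
            nrow(filtered$counts), nrow(rna$counts)))

deg <- call_differential_expression(filtered, c("E2D", "CTR"))
write_result_table(deg, file.path(outdir, "deg.tsv"))
called <- deg[deg$called, ]
cat(sprintf("%d DEGs (E2D vs CTR): %.1f%% down-regulated\n",
            nrow(called), 100 * mean(called$direction == "down")))

deg_rest <- call_differential_expression(filtered, c("ReSt", "CTR"))
write_result_table(deg_rest, file.path(outdir, "deg_rest.tsv"))
cat(sprintf("%d DEGs remain vs CTR after re-stimulation\n",
            sum(deg_rest$called)))
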