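#!/usr/bin/env Rscript
# Genomic context of the called DMPs: feature annotation (promoter/exon/
# intron/intergenic), CpG island/shore/shelf classes, nearest genes, and the
# differential/expected overlap fold-enrichment against the planted TF set
# with Fisher exact significance (alpha 1e-5) over the all-probe background.

suppressMessages(library(estroepi))
outdir <- "results/run"

dmp <- read_result_table(file.path(outdir, "dmp.tsv"))
called <- dmp[dmp$called, ]
genes <- read_bed(file.path(outdir, "genes.bed"), name = "genes")
promoters <- read_bed(file.path(outdir, "promoters.bed"), name = "promoters")
exons <- read_bed(file.path(outdir, "exons.bed"), name = "exons")
islands <- read_bed(file.path(outdir, "cpg_islands.bed"), name = "cpg_islands")
tf <- read_bed(file.path(outdir, "tf_planted.bed"), name = "tf_planted")

hits <- interval_set(called$chrom, called$pos, called$pos + 1,
                     name = "dmps", id = called$probe_id)
feats <- annotate_features(hits, genes, promoters, exons)
cpg <- cpg_density_class(hits, islands)
nearest <- nearest_gene(hits, genes)
context <- data.frame(probe_id = called$probe_id, feature = feats,
                      cpg_class = cpg, nearest_gene = nearest$gene_id,
                      gene_distance = nearest$distance)
write_result_table(context, file.path(outdir, "dmp_context.tsv"))
cat("feature distribution of called DMPs:\n")
print(round(100 * prop.table(table(feats)), 1))
cat("CpG density classes:\n")
print(round(100 * prop.table(table(cpg)), 1))

background <- interval_set(dmp$chrom, dmp$pos, dmp$pos + 1,
                           name = "all_probes", id = dmp$probe_id)
enr <- rbind(overlap_enrichment(hits, background, tf),
             overlap_enrichment(hits, background, islands))
write_result_table(enr, file.path(outdir, "enrichment.tsv"))
cat(sprintf("TF-set enrichment: %.2f-fold (Fisher p = %.3g, significant at 1e-5: %s)\n",
            enr$fold[1], enr$fisher_p[1], enr$significant[1]))
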