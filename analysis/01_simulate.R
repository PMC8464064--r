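#!/usr/bin/env Rscript
# Generate the synthetic study: a methylome with time-growing planted
# hypermethylation under estradiol deprivation (plus a partially-retained
# re-stimulation arm), a genomic annotation bundle with one TF set planted
# at 9-fold enrichment over the planted probes, and NB read counts for
# H3K27ac regions and genes with majority-down planted effects.
#
# Writes every downstream input under results/run/ as TSV/BED/JSON.

suppressMessages(library(estroepi))
seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
outdir <- "results/run"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

sim <- simulate_methylome(cfg)
write_methylation(sim$methylome, file.path(outdir, "betas.tsv"),
                  file.path(outdir, "samples.tsv"))

ann <- simulate_annotation(cfg)
for (nm in names(ann)) write_bed(ann[[nm]], file.path(outdir, paste0(nm, ".bed")))

chip <- simulate_counts(cfg, "chip")
write_counts(chip$counts, file.path(outdir, "chip_counts.tsv"),
             file.path(outdir, "chip_samples.tsv"))
rna <- simulate_counts(cfg, "rna")
write_counts(rna$counts, file.path(outdir, "rna_counts.tsv"),
             file.path(outdir, "rna_samples.tsv"))

truth <- c(sim$truth, list(db = chip$truth, de = rna$truth))
jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d probes (%d hyper + %d hypo planted), %d genes, %d regions\n",
            cfg$n_probes, cfg$n_planted_hyper, cfg$n_planted_hypo,
            cfg$n_genes, cfg$n_regions))
cat("inputs written under", outdir, "\n")
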