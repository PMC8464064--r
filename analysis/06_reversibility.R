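#!/usr/bin/env Rscript
# Reversibility after re-stimulation: quartile-stratified recovery of the
# hypermethylated DMPs (quartiles of control baseline methylation at d14)
# and persistence classification (reversed / retained / new) for DMPs,
# DB regions and DEGs. DMP retention uses the effect-size mode (delta-beta
# comparable to the deprived arm), the reading suited to estimating the
# retained fraction at this replication level.

suppressMessages(library(estroepi))
outdir <- "results/run"

mset <- read_methylation(file.path(outdir, "betas.tsv"),
                         file.path(outdir, "samples.tsv"))
dmp <- read_result_table(file.path(outdir, "dmp.tsv"))
called <- dmp[dmp$called, ]
hyper_ids <- called$probe_id[called$direction == "hyper"]

qs <- quartile_recovery(mset, hyper_ids)
write_result_table(qs$by_quartile, file.path(outdir, "quartiles.tsv"))
print(qs)

d14 <- subset_methylation(mset, samples = mset$samples$timepoint == "d14")
rest <- call_effects(fit_treatment_model(d14, c("ReSt", "CTR")))
pers_dmp <- classify_persistence(called[, c("probe_id", "direction")],
                                 rest[rest$called, c("probe_id", "direction")])

db <- read_result_table(file.path(outdir, "db.tsv"))
db_rest <- read_result_table(file.path(outdir, "db_rest.tsv"))
pers_db <- classify_persistence(db[db$called, c("unit_id", "direction")],
                                db_rest[db_rest$called, c("unit_id", "direction")])

deg <- read_result_table(file.path(outdir, "deg.tsv"))
deg_rest <- read_result_table(file.path(outdir, "deg_rest.tsv"))
pers_deg <- classify_persistence(deg[deg$called, c("unit_id", "direction")],
                                 deg_rest[deg_rest$called, c("unit_id", "direction")])

report <- recovery_report(pers_dmp, pers_db, pers_deg)
write_result_table(report, file.path(outdir, "persistence.tsv"))

for (nm in c("methylation", "h3k27ac", "expression")) {
  sub <- report[report$assay == nm, ]
  ct <- table(factor(sub$status, levels = c("reversed", "retained", "new")))
  cat(sprintf("%s: %d reversed, %d retained, %d new (retained fraction %.2f)\n",
              nm, ct["reversed"], ct["retained"], ct["new"],
              ct["retained"] / max(1, ct["retained"] + ct["reversed"])))
}
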