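# End-to-end orchestration of the synthetic study: simulate inputs, call
# DMPs with the permutation control, run the enrichment machinery, call
# differential binding and expression, classify reversibility, and write a
# manifest of content digests so repeat runs are verifiably identical.

#' Per-stage thresholds for a pipeline run
#'
#' Defaults are the published values: FDR 0.05 and delta-beta 0.10 for DMPs,
#' |log2FC| 1 for differential binding and expression, Fisher alpha 1e-5,
#' peak filters (< 1.5 kb, q < 0.01, fold > 5), CPM > 10 in >= 2 samples,
#' 10 permutation shuffles, 250 bp windows around DMPs.
#'
#' @param fdr,delta,lfc,alpha,cpm_min,cpm_min_samples,peak_max_width,
#'   peak_q_max,peak_min_fold,n_shuffles,expand_dmp stage thresholds.
#' @return validated list of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(fdr = 0.05, delta = 0.10, lfc = 1.0,
                                alpha = 1e-5, cpm_min = 10,
                                cpm_min_samples = 2, peak_max_width = 1500,
                                peak_q_max = 0.01, peak_min_fold = 5,
                                n_shuffles = 10, expand_dmp = 250) {
  check_fraction(fdr, "fdr", open_left = TRUE, open_right = TRUE)
  check_fraction(delta, "delta", open_left = TRUE, open_right = TRUE)
  check_positive(lfc, "lfc")
  check_fraction(alpha, "alpha", open_left = TRUE)
  check_positive(cpm_min, "cpm_min")
  check_count(cpm_min_samples, "cpm_min_samples", min = 1L)
  check_positive(peak_max_width, "peak_max_width")
  check_fraction(peak_q_max, "peak_q_max", open_left = TRUE)
  check_positive(peak_min_fold, "peak_min_fold")
  check_count(n_shuffles, "n_shuffles", min = 1L)
  check_positive(expand_dmp, "expand_dmp")
  structure(as.list(environment()), class = "pipeline_thresholds")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> dmp (+ permutation control) -> enrichment -> chip DB
#' -> rna DE -> reversibility in dependency order under one master seed,
#' writes every stage output as TSV/BED/JSON under `outdir`, and returns a
#' manifest listing each file with its md5 digest. Re-running with the same
#' configuration reproduces identical digests.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param outdir output directory (created if needed).
#' @param thresholds a [pipeline_thresholds()].
#' @param streams subset of `c("methylome", "chip", "rna")` to run; stages
#'   whose stream is absent are marked "skipped" in the manifest.
#' @return the manifest (list with `stages`, `files`, `seed`), invisibly
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         thresholds = pipeline_thresholds(),
                         streams = c("methylome", "chip", "rna")) {
  stopifnot(inherits(config, "sim_config"),
            inherits(thresholds, "pipeline_thresholds"))
  streams <- match.arg(streams, several.ok = TRUE)
  if (!"methylome" %in% streams)
    stop_param("the methylome stream is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- thresholds
  stages <- list()
  outputs <- character(0)
  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path

  # --- simulate ---------------------------------------------------------
  sim <- simulate_methylome(config)
  ann <- simulate_annotation(config)
  write_methylation(sim$methylome, file.path(outdir, "betas.tsv"),
                    file.path(outdir, "samples.tsv"))
  emit(file.path(outdir, "betas.tsv")); emit(file.path(outdir, "samples.tsv"))
  for (nm in names(ann)) {
    p <- file.path(outdir, paste0(nm, ".bed"))
    write_bed(ann[[nm]], p); emit(p)
  }
  truth <- sim$truth
  chip <- rna <- NULL
  if ("chip" %in% streams) {
    chip <- simulate_counts(config, "chip")
    write_counts(chip$counts, file.path(outdir, "chip_counts.tsv"),
                 file.path(outdir, "chip_samples.tsv"))
    emit(file.path(outdir, "chip_counts.tsv"))
    emit(file.path(outdir, "chip_samples.tsv"))
    truth$db <- chip$truth
  }
  if ("rna" %in% streams) {
    rna <- simulate_counts(config, "rna")
    write_counts(rna$counts, file.path(outdir, "rna_counts.tsv"),
                 file.path(outdir, "rna_samples.tsv"))
    emit(file.path(outdir, "rna_counts.tsv"))
    emit(file.path(outdir, "rna_samples.tsv"))
    truth$de <- rna$truth
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  emit(file.path(outdir, "truth.json"))
  stages$simulate <- "ok"

  # --- dmp --------------------------------------------------------------
  mset <- filter_probes(sim$methylome, 0.01)
  fit_dep <- fit_treatment_model(mset, c("E2D", "CTR"))
  dmp <- call_dmps(fit_dep, th$fdr, th$delta)
  write_result_table(dmp, file.path(outdir, "dmp.tsv"))
  emit(file.path(outdir, "dmp.tsv"))
  perm <- permutation_null(mset, th$n_shuffles, seed = config$seed,
                           fdr_max = th$fdr, delta_min = th$delta)
  write.table(data.frame(shuffle = seq_along(perm), dmp_count = perm),
              file.path(outdir, "permutation_null.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit(file.path(outdir, "permutation_null.tsv"))
  stages$dmp <- "ok"

  # --- enrichment -------------------------------------------------------
  called <- dmp[dmp$called, , drop = FALSE]
  all_probes <- probes_as_intervals(mset$probes)
  enr <- NULL
  if (nrow(called) > 0) {
    hits <- interval_set(called$chrom, called$pos, called$pos + 1,
                         name = "dmps", id = called$probe_id)
    enr <- rbind(
      overlap_enrichment(hits, all_probes, ann$tf_planted, th$alpha),
      overlap_enrichment(hits, all_probes, ann$cpg_islands, th$alpha))
    feats <- annotate_features(hits, ann$genes, ann$promoters, ann$exons)
    cpg <- cpg_density_class(hits, ann$cpg_islands)
    write_result_table(
      data.frame(probe_id = called$probe_id, feature = feats,
                 cpg_class = cpg),
      file.path(outdir, "dmp_context.tsv"))
    emit(file.path(outdir, "dmp_context.tsv"))
    write_result_table(enr, file.path(outdir, "enrichment.tsv"))
    emit(file.path(outdir, "enrichment.tsv"))
  }
  stages$enrichment <- if (is.null(enr)) "no DMPs" else "ok"

  # --- chip DB ----------------------------------------------------------
  db <- db_rest <- NULL
  if ("chip" %in% streams) {
    db <- call_differential_binding(chip$counts, c("E2D", "CTR"),
                                    th$fdr, th$lfc)
    write_result_table(db, file.path(outdir, "db.tsv"))
    emit(file.path(outdir, "db.tsv"))
    db_rest <- call_differential_binding(chip$counts, c("ReSt", "CTR"),
                                         th$fdr, th$lfc)
    write_result_table(db_rest, file.path(outdir, "db_rest.tsv"))
    emit(file.path(outdir, "db_rest.tsv"))
    stages$chip_db <- "ok"
  } else stages$chip_db <- "skipped"

  # --- rna DE -----------------------------------------------------------
  deg <- deg_rest <- NULL
  if ("rna" %in% streams) {
    filtered <- filter_low_expression(rna$counts, th$cpm_min,
                                      th$cpm_min_samples)
    dropped <- attr(filtered, "filtered_out")
    write_result_table(
      data.frame(unit_id = dropped,
                 reason = rep("low_expression", length(dropped))),
      file.path(outdir, "rna_filter_audit.tsv"))
    emit(file.path(outdir, "rna_filter_audit.tsv"))
    deg <- call_differential_expression(filtered, c("E2D", "CTR"),
                                        fdr_max = th$fdr, lfc_min = th$lfc)
    write_result_table(deg, file.path(outdir, "deg.tsv"))
    emit(file.path(outdir, "deg.tsv"))
    deg_rest <- call_differential_expression(
      filtered, c("ReSt", "CTR"), fdr_max = th$fdr, lfc_min = th$lfc)
    write_result_table(deg_rest, file.path(outdir, "deg_rest.tsv"))
    emit(file.path(outdir, "deg_rest.tsv"))
    stages$rna_de <- "ok"
  } else stages$rna_de <- "skipped"

  # --- reversibility ----------------------------------------------------
  hyper_ids <- called$probe_id[called$direction == "hyper"]
  if (length(hyper_ids) >= 4) {
    qs <- quartile_recovery(mset, hyper_ids)
    write_result_table(qs$by_quartile, file.path(outdir, "quartiles.tsv"))
    emit(file.path(outdir, "quartiles.tsv"))
  }
  fit_rest <- fit_treatment_model(
    subset_methylation(mset, samples = mset$samples$timepoint == "d14"),
    c("ReSt", "CTR"))
  dmp_rest <- call_effects(fit_rest, th$delta)
  pers_dmp <- classify_persistence(called[, c("probe_id", "direction")],
                                   dmp_rest[dmp_rest$called,
                                            c("probe_id", "direction")])
  pers_db <- if (!is.null(db))
    classify_persistence(db[db$called, c("unit_id", "direction")],
                         db_rest[db_rest$called, c("unit_id", "direction")])
  pers_deg <- if (!is.null(deg))
    classify_persistence(deg[deg$called, c("unit_id", "direction")],
                         deg_rest[deg_rest$called, c("unit_id", "direction")])
  report <- recovery_report(pers_dmp, pers_db, pers_deg)
  write_result_table(report, file.path(outdir, "persistence.tsv"))
  emit(file.path(outdir, "persistence.tsv"))
  stages$reversibility <- "ok"

  manifest <- list(
    seed = config$seed,
    stages = stages,
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Counts table of the run's calls: DMPs by direction, DB regions by
#' direction, DEGs by direction, persistence statuses and top enrichments.
#'
#' @param outdir directory written by [run_pipeline()].
#' @return data.frame with `quantity` and `value` columns.
#' @export
summarize_run <- function(outdir) {
  rows <- list()
  add <- function(q, v) rows[[length(rows) + 1L]] <<- data.frame(
    quantity = q, value = v, stringsAsFactors = FALSE)
  tab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) read_result_table(p) else NULL
  }
  dmp <- tab("dmp.tsv")
  if (!is.null(dmp)) {
    add("dmp_total", sum(dmp$called))
    add("dmp_hyper", sum(dmp$called & dmp$direction == "hyper", na.rm = TRUE))
    add("dmp_hypo", sum(dmp$called & dmp$direction == "hypo", na.rm = TRUE))
  }
  perm <- tab("permutation_null.tsv")
  if (!is.null(perm)) add("permutation_max_dmps", max(perm$dmp_count))
  db <- tab("db.tsv")
  if (!is.null(db)) {
    add("db_total", sum(db$called))
    add("db_loss", sum(db$called & db$direction == "loss", na.rm = TRUE))
    add("db_gain", sum(db$called & db$direction == "gain", na.rm = TRUE))
  }
  deg <- tab("deg.tsv")
  if (!is.null(deg)) {
    add("deg_total", sum(deg$called))
    add("deg_down", sum(deg$called & deg$direction == "down", na.rm = TRUE))
    add("deg_up", sum(deg$called & deg$direction == "up", na.rm = TRUE))
  }
  pers <- tab("persistence.tsv")
  if (!is.null(pers)) {
    for (s in c("reversed", "retained", "new"))
      add(paste0("persistence_", s), sum(pers$status == s))
  }
  enr <- tab("enrichment.tsv")
  if (!is.null(enr)) {
    for (i in seq_len(nrow(enr)))
      add(paste0("fold_", enr$set_name[i]), enr$fold[i])
  }
  if (!length(rows))
    return(data.frame(quantity = character(0), value = numeric(0)))
  do.call(rbind, rows)
}
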