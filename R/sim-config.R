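#' Simulation configuration for the synthetic study design
#'
#' Builds the parameter object consumed by [simulate_methylome()],
#' [simulate_annotation()] and [simulate_counts()]. The defaults reproduce the
#' study design the pipeline targets: continuously estradiol-stimulated
#' controls (CTR) sampled at days 0, 4 and 14, estradiol-deprived cells (E2D)
#' at days 4 and 14, and a deprived-then-re-stimulated arm (ReSt) at day 14,
#' all in triplicate — i.e. a 9-sample CTR vs 6-sample E2D contrast adjusted
#' for timepoint, plus 3 ReSt samples.
#'
#' Planted hypermethylation grows with time in deprivation (`delta_d4` at day
#' 4, `delta_d14` at day 14) and reverts on re-stimulation except for a
#' `retained_fraction` of planted probes which keep the day-4 effect. Probe
#' noise is beta-distributed around the condition mean with concentration
#' `noise_precision` (a concentration of 300 corresponds to a within-group
#' beta SD of roughly 0.03 at intermediate methylation, typical of cell-line
#' replicates on methylation arrays).
#'
#' @param n_probes number of CpG probes.
#' @param n_planted_hyper,n_planted_hypo numbers of probes planted hyper-/
#'   hypomethylated under deprivation. The defaults keep 95% of planted
#'   effects hypermethylated.
#' @param delta_d4,delta_d14 planted beta-scale effects at day 4 and day 14;
#'   must satisfy `0 < delta_d4 <= delta_d14 < 1` (effects grow with time).
#' @param noise_precision beta-distribution concentration of probe noise.
#' @param design data.frame with columns `treatment`, `timepoint`,
#'   `n_replicates` describing the sample layout.
#' @param retained_fraction fraction of planted effects persisting in ReSt.
#' @param retention_mode how retained probes are chosen among planted ones:
#'   `"random"` or `"high_baseline"` (retention concentrated in probes with
#'   the highest baseline methylation).
#' @param genome data.frame with columns `chrom`, `length` (bp).
#' @param n_genes,n_regions numbers of expression units and ChIP consensus
#'   regions for the count simulators.
#' @param n_planted_de,n_planted_db numbers of planted differential
#'   expression/binding units.
#' @param de_fraction_down,db_fraction_down fractions of planted DE/DB units
#'   that are down-regulated/lose signal under deprivation.
#' @param effect_lfc absolute planted log2 fold-change of DE/DB units.
#' @param nb_dispersion negative-binomial dispersion of RNA counts.
#' @param chip_dispersion negative-binomial dispersion of ChIP region counts
#'   (consensus-peak counts across cell-line replicates are far less dispersed
#'   than RNA biological replicates).
#' @param enrichment_fold_planted target overlap fold-enrichment of the
#'   planted TF interval set at planted probes, measured against the
#'   all-probe background.
#' @param tf_background_rate background coverage rate of the planted TF set.
#' @param seed master seed; every stream of randomness in the generators is
#'   derived deterministically from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 1000, n_planted_hyper = 50, seed = 7)
#' cfg$design
sim_config <- function(n_probes = 20000L,
                       n_planted_hyper = 500L,
                       n_planted_hypo = 25L,
                       delta_d4 = 0.15,
                       delta_d14 = 0.20,
                       noise_precision = 300,
                       design = default_design(),
                       retained_fraction = 0.2,
                       retention_mode = c("random", "high_baseline"),
                       genome = default_genome(),
                       n_genes = 5000L,
                       n_regions = 2000L,
                       n_planted_de = 400L,
                       n_planted_db = 200L,
                       de_fraction_down = 0.7,
                       db_fraction_down = 0.85,
                       effect_lfc = 2,
                       nb_dispersion = 0.1,
                       chip_dispersion = 0.005,
                       enrichment_fold_planted = 9,
                       tf_background_rate = 0.05,
                       seed = 1L) {
  retention_mode <- match.arg(retention_mode)
  n_probes <- check_count(n_probes, "n_probes", min = 1L)
  n_planted_hyper <- check_count(n_planted_hyper, "n_planted_hyper")
  n_planted_hypo <- check_count(n_planted_hypo, "n_planted_hypo")
  if (n_planted_hyper + n_planted_hypo > n_probes)
    stop_param("planted probes (%d) exceed n_probes (%d)",
               n_planted_hyper + n_planted_hypo, n_probes)
  if (!(delta_d4 > 0 && delta_d4 <= delta_d14 && delta_d14 < 1) &&
      !(delta_d4 == 0 && delta_d14 == 0))
    stop_param("effects must satisfy 0 < delta_d4 <= delta_d14 < 1 (or both 0)")
  check_positive(noise_precision, "noise_precision")
  check_fraction(retained_fraction, "retained_fraction")
  stopifnot(is.data.frame(design),
            all(c("treatment", "timepoint", "n_replicates") %in% names(design)))
  if (any(design$n_replicates < 1)) stop_param("n_replicates must be >= 1")
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (any(genome$length <= 0)) stop_param("every chrom length must be > 0")
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  n_planted_de <- check_count(n_planted_de, "n_planted_de")
  n_planted_db <- check_count(n_planted_db, "n_planted_db")
  if (n_planted_de > n_genes) stop_param("n_planted_de exceeds n_genes")
  if (n_planted_db > n_regions) stop_param("n_planted_db exceeds n_regions")
  check_fraction(de_fraction_down, "de_fraction_down")
  check_fraction(db_fraction_down, "db_fraction_down")
  check_positive(effect_lfc, "effect_lfc")
  check_positive(nb_dispersion, "nb_dispersion")
  check_positive(chip_dispersion, "chip_dispersion")
  check_positive(enrichment_fold_planted, "enrichment_fold_planted")
  check_fraction(tf_background_rate, "tf_background_rate", open_left = TRUE,
                 open_right = TRUE)
  seed <- check_count(seed, "seed")

  structure(list(
    n_probes = n_probes, n_planted_hyper = n_planted_hyper,
    n_planted_hypo = n_planted_hypo, delta_d4 = delta_d4,
    delta_d14 = delta_d14, noise_precision = noise_precision,
    design = design, retained_fraction = retained_fraction,
    retention_mode = retention_mode, genome = genome, n_genes = n_genes,
    n_regions = n_regions, n_planted_de = n_planted_de,
    n_planted_db = n_planted_db, de_fraction_down = de_fraction_down,
    db_fraction_down = db_fraction_down, effect_lfc = effect_lfc,
    nb_dispersion = nb_dispersion, chip_dispersion = chip_dispersion,
    enrichment_fold_planted = enrichment_fold_planted,
    tf_background_rate = tf_background_rate, seed = seed
  ), class = "sim_config")
}

#' Default sample layout: CTR in triplicate at d0/d4/d14, E2D at d4/d14,
#' ReSt at d14.
#' @return data.frame with treatment, timepoint and replicate counts.
#' @export
default_design <- function() {
  data.frame(
    treatment  = c("CTR", "CTR", "CTR", "E2D", "E2D", "ReSt"),
    timepoint  = c("d0", "d4", "d14", "d4", "d14", "d14"),
    n_replicates = 3L,
    stringsAsFactors = FALSE
  )
}

#' Default two-chromosome synthetic genome (100 Mb).
#' @return data.frame with chrom and length columns.
#' @export
default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(6e7, 4e7),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_probes, "probes,",
      x$n_planted_hyper, "planted hyper /", x$n_planted_hypo, "hypo,",
      sprintf("effects %.2f (d4) -> %.2f (d14),", x$delta_d4, x$delta_d14),
      "\n  ", sum(x$design$n_replicates), "samples;",
      x$n_genes, "genes,", x$n_regions, "ChIP regions; seed", x$seed, "\n")
  invisible(x)
}

# Expand the design into a per-sample sheet.
sample_sheet <- function(config) {
  d <- config$design
  rows <- lapply(seq_len(nrow(d)), function(i) {
    data.frame(
      treatment = d$treatment[i], timepoint = d$timepoint[i],
      replicate = seq_len(d$n_replicates[i]), stringsAsFactors = FALSE
    )
  })
  sheet <- do.call(rbind, rows)
  sheet$sample_id <- paste(sheet$treatment, sheet$timepoint,
                           paste0("r", sheet$replicate), sep = "_")
  sheet[, c("sample_id", "treatment", "timepoint", "replicate")]
}
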