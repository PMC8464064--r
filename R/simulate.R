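# Synthetic-data generators. Every stream of randomness derives its own
# sub-seed from config$seed so that stages are individually reproducible and
# never perturb one another (or the caller's RNG state).

#' Simulate a methylome with planted deprivation effects
#'
#' Draws per-probe baseline beta means from a bimodal mixture spanning (0,1),
#' plants hypermethylation (baseline in `[0.4, 0.7]`, mirroring the
#' intermediate methylation typical of enhancer CpGs) that grows from day 4 to
#' day 14 in deprived samples, and reverts the effect on re-stimulation except
#' for a retained subset which keeps the day-4 effect. Observed betas are
#' beta-distributed around the condition mean with concentration
#' `noise_precision`.
#'
#' @param config a [sim_config()].
#' @return list with elements `methylome` (a [methylation_set()]) and `truth`
#'   (list of planted probe id vectors: `planted_hyper_ids`,
#'   `planted_hypo_ids`, `retained_ids`).
#' @export
#' @examples
#' sim <- simulate_methylome(sim_config(n_probes = 500, n_planted_hyper = 20,
#'                                      n_planted_hypo = 2, seed = 3))
#' sim$methylome
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- sample_sheet(config)
  n <- config$n_probes
  probes <- simulate_probe_positions(config)

  base <- with_seed(derive_seed(config$seed, "baseline"), {
    comp <- sample(c("low", "mid", "high"), n, replace = TRUE,
                   prob = c(0.4, 0.2, 0.4))
    b <- numeric(n)
    b[comp == "low"] <- rbeta(sum(comp == "low"), 2, 18)
    b[comp == "mid"] <- runif(sum(comp == "mid"), 0.2, 0.8)
    b[comp == "high"] <- rbeta(sum(comp == "high"), 18, 2)
    b
  })

  planted <- with_seed(derive_seed(config$seed, "planted"), {
    idx <- sample.int(n, config$n_planted_hyper + config$n_planted_hypo)
    hyper <- idx[seq_len(config$n_planted_hyper)]
    hypo <- setdiff(idx, hyper)
    # planted sites get intermediate baselines so effects stay inside (0,1)
    bs <- runif(length(idx), 0.4, 0.7)
    list(hyper = hyper, hypo = hypo, baseline = bs)
  })
  base[c(planted$hyper, planted$hypo)] <- planted$baseline

  sign_vec <- numeric(n)
  sign_vec[planted$hyper] <- 1
  sign_vec[planted$hypo] <- -1

  n_planted <- length(planted$hyper) + length(planted$hypo)
  retained_idx <- integer(0)
  if (n_planted > 0 && config$retained_fraction > 0) {
    k <- round(config$retained_fraction * n_planted)
    all_planted <- c(planted$hyper, planted$hypo)
    retained_idx <- if (config$retention_mode == "high_baseline") {
      all_planted[order(base[all_planted], decreasing = TRUE)][seq_len(k)]
    } else {
      with_seed(derive_seed(config$seed, "retained"),
                sample(all_planted, k))
    }
  }

  effect_at <- function(treatment, timepoint) {
    delta <- numeric(n)
    if (treatment == "E2D") {
      d <- switch(timepoint, d4 = config$delta_d4, d14 = config$delta_d14, 0)
      delta <- sign_vec * d
    } else if (treatment == "ReSt") {
      delta[retained_idx] <- sign_vec[retained_idx] * config$delta_d4
    }
    delta
  }

  mu <- sapply(seq_len(nrow(sheet)), function(j) {
    m <- base + effect_at(sheet$treatment[j], sheet$timepoint[j])
    if (any(m <= 0 | m >= 1))
      stop_param("planted effect pushes a probe mean outside (0,1); reduce the effect or adjust baselines")
    m
  })

  beta <- with_seed(derive_seed(config$seed, "noise"), {
    prec <- config$noise_precision
    matrix(rbeta(length(mu), c(mu) * prec, (1 - c(mu)) * prec),
           nrow = n, ncol = nrow(sheet))
  })
  detection_p <- with_seed(derive_seed(config$seed, "detp"),
                           matrix(runif(length(beta), 0, 0.005),
                                  nrow = n, ncol = nrow(sheet)))

  truth <- list(
    planted_hyper_ids = probes$probe_id[planted$hyper],
    planted_hypo_ids = probes$probe_id[planted$hypo],
    retained_ids = probes$probe_id[retained_idx]
  )
  list(methylome = methylation_set(beta, probes, sheet, detection_p),
       truth = truth)
}

# Uniform probe positions over the genome (excluding each chromosome's last
# base, so a width-1 probe interval always fits). Shared — via the same
# derived seed — by simulate_methylome() and simulate_annotation().
simulate_probe_positions <- function(config) {
  g <- config$genome
  with_seed(derive_seed(config$seed, "probes"), {
    chrom <- sample(g$chrom, config$n_probes, replace = TRUE,
                    prob = g$length / sum(g$length))
    len <- g$length[match(chrom, g$chrom)]
    pos <- floor(runif(config$n_probes, 0, len - 1))
    ord <- order(chrom, pos)
    data.frame(probe_id = sprintf("cg%07d", seq_len(config$n_probes)),
               chrom = chrom[ord], pos = pos[ord], stringsAsFactors = FALSE)
  })
}

#' Simulate a genomic annotation bundle
#'
#' Generates gene models (genes, promoters, exons, introns), CpG islands,
#' a chromatin-state segmentation and one "TF" binding set planted to cover
#' planted probes at `enrichment_fold_planted` times the all-probe background
#' coverage rate (the calibration solves for the per-probe coverage
#' probability such that the downstream differential/expected fold — hits%
#' over background% with the background including the hits — equals the
#' target in expectation).
#'
#' @param config a [sim_config()].
#' @return named list of [interval_set()]s: `genes`, `promoters`, `exons`,
#'   `introns`, `cpg_islands`, `chromhmm`, `tf_planted`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  probes <- simulate_probe_positions(config)

  genes <- with_seed(derive_seed(config$seed, "genes"), {
    n_per <- pmax(1L, round(config$n_genes * g$length / sum(g$length)))
    # trim rounding overshoot from the largest chromosome
    while (sum(n_per) > config$n_genes) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
    rows <- lapply(seq_len(nrow(g)), function(i) {
      k <- n_per[i]
      len <- round(runif(k, 2000, 10000))
      slack <- g$length[i] - sum(len) - 4000 * (k + 1)
      if (slack < 0)
        stop_param("genome too small to place %d genes on %s", k, g$chrom[i])
      gaps <- 4000 + floor(slack * rexp_norm(k))
      start <- cumsum(gaps) + cumsum(c(0, head(len, -1)))
      data.frame(chrom = g$chrom[i], start = start, end = start + len,
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$id <- sprintf("g%05d", seq_len(nrow(df)))
    df
  })
  gene_set <- interval_set(genes$chrom, genes$start, genes$end, name = "genes",
                           id = genes$id, strand = genes$strand)

  prom <- promoter_windows(gene_set, upstream = 2000, downstream = 500,
                           genome = g)

  exon_rows <- with_seed(derive_seed(config$seed, "exons"), {
    out <- lapply(seq_len(nrow(genes)), function(i) {
      glen <- genes$end[i] - genes$start[i]
      k <- sample(2:5, 1)
      block <- glen / k
      es <- genes$start[i] + round((seq_len(k) - 1) * block)
      ee <- es + pmax(50, round(runif(k, 0.15, 0.4) * block))
      data.frame(chrom = genes$chrom[i], start = es,
                 end = pmin(ee, genes$end[i]), gene = genes$id[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  exon_set <- interval_set(exon_rows$chrom, exon_rows$start, exon_rows$end,
                           name = "exons", id = exon_rows$gene)

  # introns = gene bodies minus exons
  gr_gene <- to_granges(gene_set)
  gr_exon <- GenomicRanges::reduce(to_granges(exon_set), ignore.strand = TRUE)
  gr_intr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(gr_gene, ignore.strand = TRUE), gr_exon,
    ignore.strand = TRUE)
  intron_set <- granges_to_intervals(gr_intr, "introns")

  islands <- with_seed(derive_seed(config$seed, "islands"), {
    k <- max(200L, round(config$n_probes / 10))
    chrom <- sample(g$chrom, k, replace = TRUE, prob = g$length / sum(g$length))
    len <- round(runif(k, 500, 2000))
    maxs <- g$length[match(chrom, g$chrom)] - len
    start <- floor(runif(k, 0, maxs))
    sort_intervals(interval_set(chrom, start, start + len,
                                name = "cpg_islands"))
  })

  chromhmm <- with_seed(derive_seed(config$seed, "chromhmm"), {
    states <- c("promoter", "enhancer", "transcribed", "repressed", "ctcf")
    rows <- lapply(seq_len(nrow(g)), function(i) {
      seg <- round(runif(ceiling(g$length[i] / 10000) + 10, 5000, 15000))
      end <- cumsum(seg)
      end <- end[end <= g$length[i]]
      end <- c(end, g$length[i])
      start <- c(0, head(end, -1))
      data.frame(chrom = g$chrom[i], start = start, end = end,
                 state = sample(states, length(start), replace = TRUE,
                                prob = c(0.1, 0.25, 0.3, 0.25, 0.1)),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    interval_set(df$chrom, df$start, df$end, name = "chromhmm",
                 state = df$state)
  })

  tf <- with_seed(derive_seed(config$seed, "tf"), {
    planted_ids <- with_planted_ids(config)
    is_planted <- probes$probe_id %in% planted_ids
    n_h <- sum(is_planted); N <- nrow(probes)
    q <- config$tf_background_rate
    f <- config$enrichment_fold_planted
    p_fg <- if (n_h == 0) q else f * q * (N - n_h) / (N - f * n_h)
    if (!is.finite(p_fg) || p_fg <= 0 || p_fg > 1)
      stop_param("enrichment_fold_planted = %.3g is unattainable at background rate %.3g with %d planted of %d probes",
                 f, q, n_h, N)
    covered <- runif(N) < ifelse(is_planted, p_fg, q)
    pos <- probes$pos[covered]
    chrom <- probes$chrom[covered]
    len <- g$length[match(chrom, g$chrom)]
    # narrow footprints: wide intervals would also sweep up neighbouring
    # probes and dilute the calibrated planted/background coverage ratio
    start <- pmax(0, pos - 10)
    end <- pmin(len, pos + 10)
    interval_set(chrom, start, end, name = "tf_planted")
  })

  list(genes = gene_set, promoters = prom, exons = exon_set,
       introns = intron_set, cpg_islands = islands, chromhmm = chromhmm,
       tf_planted = tf)
}

# normalized spacings summing to (just under) 1
rexp_norm <- function(k) {
  if (k == 0) return(numeric(0))
  e <- -log(runif(k))
  e / (sum(e) + -log(runif(1)))
}

# Planted probe ids, regenerated deterministically from the config (used by
# simulate_annotation without re-simulating betas).
with_planted_ids <- function(config) {
  n <- config$n_probes
  probes <- simulate_probe_positions(config)
  planted <- with_seed(derive_seed(config$seed, "planted"), {
    idx <- sample.int(n, config$n_planted_hyper + config$n_planted_hypo)
    idx
  })
  probes$probe_id[planted]
}

# Strand-aware promoter windows [TSS - upstream, TSS + downstream), clipped
# to chromosome bounds.
promoter_windows <- function(genes, upstream = 2000, downstream = 500,
                             genome = NULL) {
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    len <- genome$length[match(genes$chrom, genome$chrom)]
    end <- pmin(end, len)
  }
  keep <- start < end
  interval_set(genes$chrom[keep], start[keep], end[keep], name = "promoters",
               id = genes$id[keep], strand = genes$strand[keep])
}

granges_to_intervals <- function(gr, name) {
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr), name = name)
}

#' Simulate RNA or ChIP read counts with planted differential units
#'
#' Counts are negative-binomial around a lognormal per-unit baseline times a
#' lognormal per-sample depth factor. Planted units carry a `2^effect_lfc`
#' fold-change in deprived samples (down in `de_fraction_down` /
#' `db_fraction_down` of them); in re-stimulated samples the effect reverts
#' except for a `retained_fraction` of planted units. ChIP counts use the
#' day-14 samples only (the timepoint at which differential binding is
#' assessed) and the lower `chip_dispersion`.
#'
#' @param config a [sim_config()].
#' @param kind `"rna"` (genes, full design) or `"chip"` (regions, d14 only).
#' @return list with `counts` (a [count_set()]) and `truth` (data.frame of
#'   planted unit ids with `direction`, plus `retained_ids`).
#' @export
simulate_counts <- function(config, kind = c("rna", "chip")) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "sim_config"))
  sheet <- sample_sheet(config)
  if (kind == "chip") sheet <- sheet[sheet$timepoint == "d14", , drop = FALSE]
  n_units <- if (kind == "rna") config$n_genes else config$n_regions
  n_planted <- if (kind == "rna") config$n_planted_de else config$n_planted_db
  frac_down <- if (kind == "rna") config$de_fraction_down else config$db_fraction_down
  disp <- if (kind == "rna") config$nb_dispersion else config$chip_dispersion

  ids <- if (kind == "rna") sprintf("gene%05d", seq_len(n_units))
         else sprintf("region%05d", seq_len(n_units))

  units <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
  if (kind == "chip") {
    g <- config$genome
    coords <- with_seed(derive_seed(config$seed, "chip_regions"), {
      chrom <- sample(g$chrom, n_units, replace = TRUE,
                      prob = g$length / sum(g$length))
      len <- g$length[match(chrom, g$chrom)]
      start <- floor(runif(n_units, 0, len - 1000))
      data.frame(chrom = chrom, start = start, end = start + 1000)
    })
    units <- cbind(units, coords)
  }

  sim <- with_seed(derive_seed(config$seed, paste0("counts_", kind)), {
    # RNA spans a wide dynamic range; deep ChIP over strong consensus peaks
    # concentrates at high counts with a tighter spread
    base <- if (kind == "rna") rlnorm(n_units, meanlog = log(200), sdlog = 1)
            else rlnorm(n_units, meanlog = log(500), sdlog = 0.5)
    depth <- rlnorm(nrow(sheet), 0, 0.15)
    planted_idx <- sample.int(n_units, n_planted)
    n_down <- round(frac_down * n_planted)
    sign <- rep(1, n_planted)
    if (n_planted > 0) sign[seq_len(n_down)] <- -1
    retained_k <- round(config$retained_fraction * n_planted)
    retained_idx <- if (retained_k > 0) planted_idx[sample.int(n_planted, retained_k)]
                    else integer(0)

    lfc <- numeric(n_units)
    lfc[planted_idx] <- sign * config$effect_lfc
    mu <- outer(base, depth)
    e2d <- sheet$treatment == "E2D"
    rest <- sheet$treatment == "ReSt"
    mu[, e2d] <- mu[, e2d] * 2^lfc
    lfc_rest <- numeric(n_units)
    lfc_rest[retained_idx] <- lfc[retained_idx]
    mu[, rest] <- mu[, rest] * 2^lfc_rest
    counts <- matrix(rnbinom(length(mu), mu = c(mu), size = 1 / disp),
                     nrow = n_units)
    storage.mode(counts) <- "integer"
    list(counts = counts, planted_idx = planted_idx, sign = sign,
         retained_idx = retained_idx)
  })

  truth <- list(
    planted = data.frame(
      unit_id = ids[sim$planted_idx],
      direction = ifelse(sim$sign < 0, "down", "up"),
      stringsAsFactors = FALSE),
    retained_ids = ids[sim$retained_idx]
  )
  list(counts = count_set(sim$counts, units, sheet, kind = kind),
       truth = truth)
}
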