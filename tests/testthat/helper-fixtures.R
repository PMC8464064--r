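# Shared fixtures and independent brute-force oracles used across test files.

# small, fast simulation configuration for structural tests
small_config <- function(seed = 42, ...) {
  args <- list(n_probes = 1500L, n_planted_hyper = 60L, n_planted_hypo = 6L,
               n_genes = 600L, n_regions = 300L, n_planted_de = 60L,
               n_planted_db = 40L,
               genome = data.frame(chrom = c("chr1", "chr2"),
                                   length = c(9e6, 6e6)),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# build a methylation_set directly from an M-value matrix (inverse logit)
mset_from_m <- function(M, treatment, timepoint = "d4") {
  beta <- 2^M / (1 + 2^M)
  n_s <- ncol(M)
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(nrow(M))),
                       chrom = "chr1", pos = seq_len(nrow(M)) * 100)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_s)),
    treatment = treatment,
    timepoint = rep_len(timepoint, n_s),
    replicate = seq_len(n_s))
  methylation_set(beta, probes, samples)
}

# independent per-probe OLS oracle via lm()
lm_oracle <- function(mset, contrast = c("E2D", "CTR")) {
  keep <- mset$samples$treatment %in% contrast
  beta <- mset$beta[, keep, drop = FALSE]
  smp <- mset$samples[keep, ]
  M <- log2(pmin(pmax(beta, 1e-6), 1 - 1e-6) /
              (1 - pmin(pmax(beta, 1e-6), 1 - 1e-6)))
  treat <- factor(smp$treatment, levels = rev(contrast))
  multi_tp <- length(unique(smp$timepoint)) > 1
  t(sapply(seq_len(nrow(M)), function(i) {
    dat <- data.frame(m = M[i, ], treat = treat, tp = factor(smp$timepoint))
    fit <- if (multi_tp) lm(m ~ treat + tp, data = dat)
           else lm(m ~ treat, data = dat)
    co <- summary(fit)$coefficients
    co[2, c("Estimate", "t value", "Pr(>|t|)")]
  }))
}

# textbook Benjamini-Hochberg step-up, brute force
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(1, adj)
  out
}

# brute-force per-site containment scan against a set of intervals
contains_oracle <- function(sites, regions) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(regions$chrom == sites$chrom[i] &
          regions$start < sites$end[i] &
          regions$end > sites$start[i])
  }, logical(1))
}

# brute-force gap between one site and every interval of a set (intervening
# bases; 0 for overlap or adjacency), NA when no interval shares the chrom
gap_oracle <- function(site, regions) {
  same <- regions[regions$chrom == site$chrom, , drop = FALSE]
  if (nrow(same) == 0) return(NA_real_)
  gap <- pmax(0, pmax(same$start - site$end, site$start - same$end))
  min(gap)
}

random_intervals <- function(n, name = "rand", chroms = c("chr1", "chr2"),
                             max_pos = 1e6, width_range = c(50, 500)) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, max_pos))
  w <- floor(runif(n, width_range[1], width_range[2]))
  interval_set(chrom, start, start + w, name = name,
               id = sprintf("iv%04d", seq_len(n)))
}
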