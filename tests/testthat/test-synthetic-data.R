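test_that("sim_config rejects invalid parameters", {
  expect_error(sim_config(delta_d4 = 0.3, delta_d14 = 0.2), "delta_d4")
  expect_error(sim_config(retained_fraction = 1.2), "retained_fraction")
  expect_error(sim_config(n_probes = 10L, n_planted_hyper = 20L), "exceed")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(noise_precision = -1), "noise_precision")
  expect_error(sim_config(genome = data.frame(chrom = "chr1", length = 0)),
               "length")
})

test_that("identical configs give bitwise-identical simulations", {
  cfg <- small_config(seed = 7)
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(a$methylome$beta, b$methylome$beta)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_counts(cfg, "rna")$counts$counts,
                   simulate_counts(cfg, "rna")$counts$counts)
  ann1 <- simulate_annotation(cfg)
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann1$tf_planted, ann2$tf_planted)
})

test_that("null methylome is calibrated: ~5% of per-probe t-tests at p<0.05", {
  cfg <- sim_config(n_probes = 5000L, n_planted_hyper = 0L,
                    n_planted_hypo = 0L, delta_d4 = 0, delta_d14 = 0,
                    seed = 19)
  sim <- simulate_methylome(cfg)
  mset <- sim$methylome
  g1 <- mset$samples$treatment == "E2D"
  g2 <- mset$samples$treatment == "CTR"
  p <- vapply(seq_len(nrow(mset$beta)), function(i)
    t.test(mset$beta[i, g1], mset$beta[i, g2])$p.value, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("noise-free limit recovers the planted day-14 effect", {
  cfg <- small_config(seed = 3, noise_precision = 1e7)
  sim <- simulate_methylome(cfg)
  mset <- sim$methylome
  d14_e2d <- mset$samples$treatment == "E2D" & mset$samples$timepoint == "d14"
  d14_ctr <- mset$samples$treatment == "CTR" & mset$samples$timepoint == "d14"
  hyper <- match(sim$truth$planted_hyper_ids, mset$probes$probe_id)
  dbeta <- rowMeans(mset$beta[hyper, d14_e2d]) -
    rowMeans(mset$beta[hyper, d14_ctr])
  expect_true(all(abs(dbeta - cfg$delta_d14) < 0.01))
})

test_that("planted effects grow from d4 to d14 and revert in ReSt except retained", {
  cfg <- small_config(seed = 5)
  sim <- simulate_methylome(cfg)
  mset <- sim$methylome
  hyper <- match(sim$truth$planted_hyper_ids, mset$probes$probe_id)
  gm <- function(tr, tp) rowMeans(
    mset$beta[hyper, mset$samples$treatment == tr &
                mset$samples$timepoint == tp, drop = FALSE])
  d4 <- mean(gm("E2D", "d4") - gm("CTR", "d4"))
  d14 <- mean(gm("E2D", "d14") - gm("CTR", "d14"))
  expect_gt(d14, d4)
  rest_delta <- gm("ReSt", "d14") - gm("CTR", "d14")
  retained <- sim$truth$planted_hyper_ids %in% sim$truth$retained_ids
  expect_gt(mean(rest_delta[retained]), 0.10)
  expect_lt(abs(mean(rest_delta[!retained])), 0.03)
})

test_that("a planted effect that escapes (0,1) is rejected", {
  cfg <- small_config(seed = 1, delta_d4 = 0.35, delta_d14 = 0.35)
  # baseline up to 0.7 plus 0.35 exceeds 1
  expect_error(simulate_methylome(cfg), "outside")
})

test_that("annotation intervals are sorted, in-bounds, and roundtrip via BED", {
  cfg <- small_config(seed = 11)
  ann <- simulate_annotation(cfg)
  for (nm in names(ann)) {
    iv <- ann[[nm]]
    expect_true(all(iv$start < iv$end), label = nm)
    expect_true(all(iv$start >= 0), label = nm)
    len <- cfg$genome$length[match(iv$chrom, cfg$genome$chrom)]
    expect_true(all(iv$end <= len), label = nm)
    expect_false(is.unsorted(order(iv$chrom, iv$start)), label = nm)
  }
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann$cpg_islands, path)
  back <- read_bed(path)
  expect_equal(back$chrom, ann$cpg_islands$chrom)
  expect_equal(back$start, ann$cpg_islands$start)
  expect_equal(back$end, ann$cpg_islands$end)
})

test_that("fold-1 TF set covers planted and background probes alike", {
  cfg <- small_config(seed = 13, enrichment_fold_planted = 1,
                      tf_background_rate = 0.3)
  sim <- simulate_methylome(cfg)
  ann <- simulate_annotation(cfg)
  planted <- c(sim$truth$planted_hyper_ids, sim$truth$planted_hypo_ids)
  probes <- probes_as_intervals(sim$methylome$probes)
  cov <- contains_oracle(probes, ann$tf_planted)
  is_pl <- probes$id %in% planted
  # rates statistically indistinguishable
  p <- fisher_exact_p(sum(cov[is_pl]), sum(!cov[is_pl]),
                      sum(cov[!is_pl]), sum(!cov[!is_pl]))
  expect_gt(p, 0.01)
})

test_that("count simulator approaches Poisson at vanishing dispersion", {
  cfg <- small_config(seed = 9, nb_dispersion = 1e-6, n_planted_de = 0L)
  rna <- simulate_counts(cfg, "rna")
  cs <- rna$counts
  e2d <- cs$samples$treatment == "E2D"
  ctr <- cs$samples$treatment == "CTR"
  # depth-corrected group means agree within Poisson error for all units
  sf <- cs$lib_size / mean(cs$lib_size)
  norm <- sweep(cs$counts, 2, sf, "/")
  m1 <- rowMeans(norm[, e2d]); m2 <- rowMeans(norm[, ctr])
  z <- (m1 - m2) / sqrt(m1 / sum(e2d) + m2 / sum(ctr))
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("planted count effects force the configured fold-change", {
  cfg <- small_config(seed = 23, nb_dispersion = 1e-4, effect_lfc = 2)
  rna <- simulate_counts(cfg, "rna")
  cs <- rna$counts
  down <- rna$truth$planted$unit_id[rna$truth$planted$direction == "down"]
  sf <- cs$lib_size / mean(cs$lib_size)
  norm <- sweep(cs$counts, 2, sf, "/")
  lfc <- log2(rowMeans(norm[down, cs$samples$treatment == "E2D"]) /
                rowMeans(norm[down, cs$samples$treatment == "CTR"]))
  # residual scatter is pure Poisson counting noise at this dispersion
  expect_lt(abs(mean(lfc) - (-2)), 0.05)
  expect_true(all(abs(lfc - (-2)) < 0.3))
  high <- rowMeans(norm[down, cs$samples$treatment == "CTR"]) > 400
  expect_true(all(abs(lfc[high] - (-2)) < 0.15))
})
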