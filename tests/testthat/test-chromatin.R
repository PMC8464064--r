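make_peaks <- function(chrom, start, end, q, fold) {
  interval_set(chrom, start, end, name = "peaks",
               id = sprintf("pk%03d", seq_along(start)),
               q_value = q, fold_from_input = fold)
}

test_that("peak filter applies the strict width, q and fold rules and is idempotent", {
  peaks <- make_peaks("chr1",
                      start = c(0, 10000, 20000, 30000),
                      end = c(1600, 10800, 20800, 31500),
                      q = c(1e-5, 0.02, 1e-3, 1e-3),
                      fold = c(10, 10, 6, 6))
  out <- filter_peaks(peaks)
  # 1600 bp: too wide; q = 0.02: fails q; width-1500 peak fails the strict <
  expect_equal(out$id, "pk003")
  expect_equal(filter_peaks(out), out)
  expect_error(filter_peaks(peaks, max_width = 0), "max_width")
})

test_that("consensus peaks: identical replicates pass, disjoint replicates vanish", {
  peaks <- make_peaks("chr1", c(1000, 5000, 9000), c(1800, 5600, 9900),
                      q = 1e-4, fold = c(8, 9, 10))
  cons <- reproducible_peaks(peaks, peaks)
  expect_equal(nrow(cons), 3)
  expect_equal(cons$start, peaks$start)
  expect_equal(cons$end, peaks$end)
  shifted <- make_peaks("chr1", c(100000, 200000), c(100500, 200500),
                        q = 1e-4, fold = 8)
  expect_equal(nrow(reproducible_peaks(peaks, shifted)), 0)
  expect_error(reproducible_peaks(peaks, peaks, 0), "reciprocal")
})

test_that("consensus matches a brute-force reciprocal-overlap matching", {
  set.seed(7)
  start_a <- sort(sample(0:1e6, 100)) * 3
  a <- make_peaks("chr1", start_a, start_a + sample(200:1200, 100, TRUE),
                  q = runif(100, 1e-6, 1e-3), fold = runif(100, 5.5, 30))
  # second replicate: jittered versions of the first plus width changes,
  # so matches, partial overlaps and misses all occur
  start_b <- pmax(0, start_a + sample(-800:800, 100, TRUE))
  b <- make_peaks("chr1", start_b, start_b + sample(200:1200, 100, TRUE),
                  q = runif(100, 1e-6, 1e-3), fold = runif(100, 5.5, 30))
  cons <- reproducible_peaks(a, b, 0.5)
  # quadratic oracle: all pairs, reciprocal overlap, same greedy order
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    inter <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (inter <= 0) next
    if (inter / (a$end[i] - a$start[i]) >= 0.5 &&
        inter / (b$end[j] - b$start[j]) >= 0.5)
      pairs <- rbind(pairs, data.frame(
        i = i, j = j, s = min(a$fold_from_input[i], b$fold_from_input[j])))
  }
  pairs <- pairs[order(-pairs$s, pairs$i, pairs$j), ]
  ua <- logical(nrow(a)); ub <- logical(nrow(b)); keep <- NULL
  for (r in seq_len(nrow(pairs))) {
    if (!ua[pairs$i[r]] && !ub[pairs$j[r]]) {
      keep <- rbind(keep, pairs[r, ])
      ua[pairs$i[r]] <- TRUE; ub[pairs$j[r]] <- TRUE
    }
  }
  oracle <- data.frame(start = pmin(a$start[keep$i], b$start[keep$j]),
                       end = pmax(a$end[keep$i], b$end[keep$j]))
  oracle <- oracle[order(oracle$start), ]
  expect_equal(cons$start, oracle$start)
  expect_equal(cons$end, oracle$end)
})

test_that("narrowPeak files roundtrip through the reader and writer", {
  peaks <- make_peaks("chr2", c(100, 900), c(700, 1400),
                      q = c(1e-4, 1e-6), fold = c(7.5, 12))
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(peaks, path)
  back <- read_narrowpeak(path)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$fold_from_input, peaks$fold_from_input)
  expect_equal(back$q_value, peaks$q_value, tolerance = 1e-6)
})

test_that("count normalization follows the median-library log2 transform", {
  counts <- matrix(c(0, 10, 100, 0, 20, 200), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  units <- data.frame(unit_id = c("u1", "u2", "u3"))
  samples <- data.frame(sample_id = c("s1", "s2"), treatment = "CTR",
                        timepoint = "d14", replicate = 1:2)
  cs <- count_set(counts, units, samples, lib_size = c(1000, 2000),
                  kind = "chip")
  Y <- normalize_counts(cs)
  # median library 1500: factors 1.5 and 0.75; count 0 maps to 0
  expect_equal(Y[1, ], c(s1 = 0, s2 = 0))
  expect_equal(Y[2, "s1"], log2(1 + 10 * 1.5))
  expect_equal(Y[3, "s2"], log2(1 + 200 * 0.75))
  # equal library sizes: scaling factor 1 everywhere
  cs_eq <- count_set(counts, units, samples, lib_size = c(1000, 1000))
  expect_equal(normalize_counts(cs_eq), log2(1 + counts),
               ignore_attr = TRUE)
  # doubling one library (with the median pinned by a third sample)
  # halves its scaled counts exactly
  counts3 <- cbind(counts, s3 = c(5L, 15L, 150L))
  samples3 <- rbind(samples, data.frame(sample_id = "s3", treatment = "CTR",
                                        timepoint = "d14", replicate = 3))
  ref <- count_set(counts3, units, samples3, lib_size = c(1000, 1000, 2000))
  dbl <- count_set(counts3, units, samples3, lib_size = c(1000, 1000, 4000))
  expect_equal(2^normalize_counts(dbl)[, "s3"] - 1,
               (2^normalize_counts(ref)[, "s3"] - 1) / 2)
})

test_that("differential binding applies joint thresholds and is antisymmetric", {
  cfg <- small_config(seed = 4)
  chip <- simulate_counts(cfg, "chip")
  db_fwd <- call_differential_binding(chip$counts, c("E2D", "CTR"))
  db_rev <- call_differential_binding(chip$counts, c("CTR", "E2D"))
  expect_equal(db_fwd$log2_fc, -db_rev$log2_fc, tolerance = 1e-12)
  expect_equal(db_fwd$p, db_rev$p, tolerance = 1e-12)
  expect_true(all(db_fwd$called == db_rev$called))
  expect_true(all(is.na(db_fwd$direction[!db_fwd$called])))
  called <- db_fwd[db_fwd$called, ]
  expect_true(all(abs(called$log2_fc) > 1))
  expect_true(all(called$fdr < 0.05))
  # identical counts in both groups: nothing called
  cs <- chip$counts
  e2d <- which(cs$samples$treatment == "E2D")
  ctr <- which(cs$samples$treatment == "CTR")
  cs$counts[, e2d] <- cs$counts[, ctr]
  cs$lib_size[e2d] <- cs$lib_size[ctr]
  expect_equal(sum(call_differential_binding(cs, c("E2D", "CTR"))$called), 0)
  expect_error(call_differential_binding(
    subset_counts(chip$counts, c(1, 4, 5, 6)), c("E2D", "CTR")), ">= 2")
})

test_that("planted binding losses are recovered with correct directions", {
  cfg <- sim_config(seed = 303)
  chip <- simulate_counts(cfg, "chip")
  db <- call_differential_binding(chip$counts, c("E2D", "CTR"))
  called <- db[db$called, ]
  truth <- chip$truth$planted
  sens <- mean(truth$unit_id %in% called$unit_id)
  fdp <- mean(!(called$unit_id %in% truth$unit_id))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
  m <- merge(called, truth, by = "unit_id")
  expect_true(all((m$direction.x == "loss") == (m$direction.y == "down")))
  # deprivation data is dominated by losses
  expect_gte(mean(called$direction == "loss"), 0.8)
})
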