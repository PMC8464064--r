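test_that("Fisher exact p matches stats::fisher.test on random tables", {
  set.seed(101)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2)
    p_impl <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    p_ref <- fisher.test(tab)$p.value
    expect_equal(p_impl, p_ref, tolerance = 1e-9)
  }
})

test_that("overlap enrichment computes the differential/expected fold and exact p", {
  # universe of 100 width-1 sites, 20 inside regions; hits = 10 with 8 inside
  bg <- interval_set("chr1", 0:99 * 1000, 0:99 * 1000 + 1, name = "bg",
                     id = sprintf("s%03d", 1:100))
  regions <- interval_set("chr1", (0:19) * 1000, (0:19) * 1000 + 1,
                          name = "reg")
  hit_rows <- c(1:8, 51:52)           # 8 overlap, 2 do not
  hits <- interval_set("chr1", (hit_rows - 1) * 1000,
                       (hit_rows - 1) * 1000 + 1, name = "hits",
                       id = sprintf("s%03d", hit_rows))
  res <- overlap_enrichment(hits, bg, regions)
  expect_equal(res$n_hits_overlap, 8)
  expect_equal(res$n_bg_overlap, 20)
  expect_equal(res$fold, (8 / 10) / (20 / 100))
  # hypergeometric-sum oracle on the same 2x2 table [8,2;12,78]
  pr <- dhyper(0:10, 10, 90, 20)
  p_oracle <- sum(pr[pr <= dhyper(8, 10, 90, 20) * (1 + 1e-7)])
  expect_equal(res$fisher_p, p_oracle, tolerance = 1e-12)

  # self-comparison: fold 1, p 1
  self <- overlap_enrichment(bg, bg, regions)
  expect_equal(self$fold, 1.0)
  expect_equal(self$fisher_p, 1.0)

  # zero hit overlap
  none <- interval_set("chr1", c(50, 60) * 1000, c(50, 60) * 1000 + 1,
                       name = "none", id = sprintf("s%03d", c(51, 61)))
  res0 <- overlap_enrichment(none, bg, regions)
  expect_equal(res0$fold, 0)
  expect_false(res0$significant)

  # hits outside the universe are rejected
  foreign <- interval_set("chr1", 1e6, 1e6 + 1, name = "f", id = "zzz")
  expect_error(overlap_enrichment(foreign, bg, regions), "subset")
})

test_that("enrichment counts are idempotent under region duplication and translation", {
  set.seed(5)
  bg <- random_intervals(300, "bg", width_range = c(1, 2))
  hits <- bg[sample(300, 60), ]
  regions <- random_intervals(40, "reg", width_range = c(2000, 8000))
  res <- overlap_enrichment(hits, bg, regions)
  dup <- interval_set(c(regions$chrom, regions$chrom),
                      c(regions$start, regions$start),
                      c(regions$end, regions$end), name = "reg")
  res_dup <- overlap_enrichment(hits, bg, dup)
  expect_equal(res$n_hits_overlap, res_dup$n_hits_overlap)
  expect_equal(res$n_bg_overlap, res_dup$n_bg_overlap)
  expect_equal(res$fisher_p, res_dup$fisher_p)
  shift <- function(x) interval_set(x$chrom, x$start + 5000, x$end + 5000,
                                    name = set_name(x),
                                    id = if ("id" %in% names(x)) x$id else NULL)
  res_sh <- overlap_enrichment(shift(hits), shift(bg), shift(regions))
  expect_equal(res_sh$fold, res$fold)
  expect_equal(res_sh$fisher_p, res$fisher_p)
})

test_that("feature annotation follows promoter > exon > intron > intergenic", {
  genes <- interval_set("chr1", c(10000, 18000), c(20000, 40000),
                        name = "genes", id = c("gA", "gB"),
                        strand = c("+", "+"))
  promoters <- promoter_windows(genes)   # gA [8000,10500), gB [16000,18500)
  exons <- interval_set("chr1", c(10000, 35000), c(11000, 36000),
                        name = "exons", id = c("gA", "gB"))
  sites <- interval_set("chr1",
                        c(17000, 10700, 12000, 40001, 9000),
                        c(17001, 10701, 12001, 40002, 9001), name = "sites")
  lab <- annotate_features(sites, genes, promoters, exons)
  # site 17000 lies in an intron of gA AND in the promoter window of gB:
  # the promoter label wins
  expect_equal(lab, c("promoter", "exon", "intron", "intergenic", "promoter"))
  expect_error(annotate_features(
    interval_set("chrX", 1, 2, name = "s"), genes, promoters, exons), "chrX")
})

test_that("feature labels equal a brute-force containment scan", {
  cfg <- small_config(seed = 17)
  ann <- simulate_annotation(cfg)
  set.seed(17)
  sites <- random_intervals(400, "sites", max_pos = 5e6,
                            width_range = c(1, 2))
  lab <- annotate_features(sites, ann$genes, ann$promoters, ann$exons)
  in_p <- contains_oracle(sites, ann$promoters)
  in_e <- contains_oracle(sites, ann$exons)
  in_g <- contains_oracle(sites, ann$genes)
  oracle <- ifelse(in_p, "promoter",
                   ifelse(in_e, "exon", ifelse(in_g, "intron", "intergenic")))
  expect_equal(lab, oracle)
})

test_that("CpG density classes follow the island/shore/shelf distance bands", {
  islands <- interval_set("chr1", c(100000, 101500), c(101000, 102500),
                          name = "cgi")   # overlapping: merged internally
  sites <- interval_set(
    "chr1",
    c(100500, 102500 + 1499, 102500 + 2999, 102500 + 4999, 100000 - 1500),
    c(100501, 102500 + 1500, 102500 + 3000, 102500 + 5000, 100000 - 1499),
    name = "sites")
  expect_equal(cpg_density_class(sites, islands),
               c("island", "shore", "shelf", "open_sea", "shore"))
})

test_that("CpG classification equals a brute-force nearest-island scan", {
  set.seed(23)
  islands <- random_intervals(60, "cgi", width_range = c(500, 2000))
  sites <- random_intervals(1000, "sites", width_range = c(1, 2))
  cls <- cpg_density_class(sites, islands)
  # merge islands by brute force
  oracle <- vapply(seq_len(nrow(sites)), function(i) {
    if (contains_oracle(sites[i, ], islands)) return("island")
    d <- gap_oracle(sites[i, ], islands)
    if (is.na(d)) "open_sea"
    else if (d < 2000) "shore" else if (d < 4000) "shelf" else "open_sea"
  }, character(1))
  expect_equal(cls, oracle)
})

test_that("window expansion centres, clips and matches the distance test", {
  probe <- interval_set("chr1", 1000, 1001, name = "p")
  out <- expand_window(probe, 250)
  expect_equal(out$start, 875)
  expect_equal(out$end, 1125)
  # clipping at the chromosome start
  edge <- expand_window(interval_set("chr1", 10, 11, name = "p"), 250)
  expect_equal(edge$start, 0)
  # expansion + intersection equals |site - region| <= width/2
  set.seed(3)
  sites <- random_intervals(200, "s", chroms = "chr1", width_range = c(1, 2))
  regions <- random_intervals(50, "r", chroms = "chr1",
                              width_range = c(1, 2))
  expanded <- expand_window(sites, 250)
  got <- contains_oracle(expanded, regions)
  # distance form of the half-open +/-125 bp window around each 1-bp site
  oracle <- vapply(seq_len(nrow(sites)), function(i) {
    d <- regions$start - sites$start[i]
    any(d >= -125 & d < 125)
  }, logical(1))
  expect_equal(got, oracle)
  expect_error(expand_window(sites, 0), "total_width")
})

test_that("proximity join matches the all-pairs scan and handles edge cases", {
  a <- interval_set("chr1", c(100, 5000), c(200, 5100), name = "a")
  expect_equal(proximity_join(a, a, 0)$fraction, 1.0)
  b_other <- interval_set("chr2", c(100), c(200), name = "b")
  expect_equal(proximity_join(a, b_other, 1e6)$fraction, 0.0)
  expect_error(proximity_join(a, a, -1), "max_gap")
  set.seed(41)
  x <- random_intervals(200, "x")
  y <- random_intervals(200, "y")
  for (gap in c(0, 1000, 10000)) {
    res <- proximity_join(x, y, gap)
    oracle <- vapply(seq_len(nrow(x)), function(i) {
      g <- gap_oracle(x[i, ], y)
      !is.na(g) && g <= gap
    }, logical(1))
    expect_equal(res$fraction, mean(oracle))
  }
})

test_that("nearest gene matches brute force with deterministic tie-breaks", {
  genes <- interval_set("chr1", c(1000, 5001, 5001), c(2000, 6001, 5501),
                        name = "g", id = c("gC", "gB", "gA"))
  inside <- interval_set("chr1", 1500, 1501, name = "s")
  expect_equal(nearest_gene(inside, genes)$gene_id, "gC")
  expect_equal(nearest_gene(inside, genes)$distance, 0)
  # site equidistant (1500 bp) between gC and the pair starting at 5001:
  # the smaller start wins
  mid <- interval_set("chr1", 3500, 3501, name = "s")
  expect_equal(nearest_gene(mid, genes)$gene_id, "gC")
  # closer to the co-started pair: lexicographic id breaks the tie
  near_pair <- interval_set("chr1", 4000, 4001, name = "s")
  expect_equal(nearest_gene(near_pair, genes)$gene_id, "gA")
  set.seed(59)
  rg <- random_intervals(80, "g", width_range = c(500, 5000))
  sites <- random_intervals(500, "s", width_range = c(1, 2))
  got <- nearest_gene(sites, rg)
  for (i in sample(500, 60)) {
    same <- rg
    gap <- vapply(seq_len(nrow(same)), function(j)
      if (same$chrom[j] != sites$chrom[i]) Inf else
        max(0, same$start[j] - sites$end[i], sites$start[i] - same$end[j]),
      numeric(1))
    best <- which(gap == min(gap))
    best <- best[order(same$start[best], same$id[best])][1]
    expect_equal(got$gene_id[i], same$id[best])
    expect_equal(got$distance[i], min(gap))
  }
})

test_that("planted 9-fold enrichment is recovered within sampling bounds", {
  cfg <- sim_config(seed = 2026)
  sim <- simulate_methylome(cfg)
  ann <- simulate_annotation(cfg)
  truth_ids <- c(sim$truth$planted_hyper_ids, sim$truth$planted_hypo_ids)
  bg <- probes_as_intervals(sim$methylome$probes)
  hits <- bg[bg$id %in% truth_ids, ]
  res <- overlap_enrichment(hits, bg, ann$tf_planted)
  expect_gte(res$fold, 7.6)
  expect_lte(res$fold, 10.4)
  expect_true(res$significant)
})
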