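# Genomic context: feature annotation with promoter > exon > intron >
# intergenic precedence, CpG island/shore/shelf classes, window expansion,
# proximity joins, nearest genes, and the differential/expected overlap
# fold-enrichment with Fisher exact significance.

#' Two-sided Fisher exact p-value by hypergeometric enumeration
#'
#' Exact two-sided p for 2x2 tables `[a, b; c, d]`: the sum of probabilities
#' of all tables with the same margins whose probability does not exceed the
#' observed one (with the conventional `1 + 1e-7` relative tie tolerance).
#' Vectorized over tables.
#'
#' @param a,b,c,d cell counts; rows are (hit, non-hit), columns are
#'   (in-region, out-of-region).
#' @return numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_exact_p(8, 2, 12, 78) # enrichment of 8/10 vs 20/100
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop_param("table cells must be non-negative integers")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
    if (m + nn == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    dens <- dhyper(support, m, nn, k)
    p_obs <- dhyper(a[i], m, nn, k)
    min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Overlap fold-enrichment of hits against a background universe
#'
#' The differential/expected statistic: the fraction of hit elements
#' intersecting at least one region (by >= 1 bp, counted once) divided by the
#' same fraction over the whole background universe (hits included, e.g. all
#' array probes). Significance is a two-sided Fisher exact test on the 2x2
#' table of hit vs background-minus-hit elements by overlap status.
#'
#' @param hits an [interval_set()]; must be a subset of `background`
#'   (matched by `id` when both carry ids, else by coordinates).
#' @param background the background universe `interval_set`.
#' @param regions non-empty `interval_set` of target regions.
#' @param alpha significance level for the `significant` flag
#'   (default `1e-5`).
#' @return one-row data.frame of class `enrichment_result`: `set_name`,
#'   `n_hits_overlap`, `n_hits`, `n_bg_overlap`, `n_bg`, `fold`, `fisher_p`,
#'   `significant`. `fold` is `NA` when the background has zero overlap.
#' @export
overlap_enrichment <- function(hits, background, regions, alpha = 1e-5) {
  check_fraction(alpha, "alpha", open_left = TRUE)
  if (nrow(regions) == 0) stop_param("regions must be non-empty")
  key <- function(x) {
    if ("id" %in% names(x) && "id" %in% names(background)) as.character(x$id)
    else paste(x$chrom, x$start, x$end)
  }
  hit_key <- key(hits); bg_key <- key(background)
  if (!all(hit_key %in% bg_key))
    stop_param("hits must be a subset of the background universe (%d foreign elements)",
               sum(!hit_key %in% bg_key))

  gr_reg <- to_granges(regions)
  bg_ov <- GenomicRanges::countOverlaps(to_granges(background), gr_reg,
                                        ignore.strand = TRUE) > 0
  hit_ov <- GenomicRanges::countOverlaps(to_granges(hits), gr_reg,
                                         ignore.strand = TRUE) > 0
  n_hits <- nrow(hits); n_bg <- nrow(background)
  nho <- sum(hit_ov); nbo <- sum(bg_ov)

  fold <- if (nbo > 0) (nho / n_hits) / (nbo / n_bg) else NA_real_
  # background-minus-hits row of the 2x2 table
  rest_in <- nbo - nho
  rest_out <- (n_bg - n_hits) - rest_in
  p <- fisher_exact_p(nho, n_hits - nho, rest_in, rest_out)

  out <- data.frame(set_name = set_name(regions),
                    n_hits_overlap = nho, n_hits = n_hits,
                    n_bg_overlap = nbo, n_bg = n_bg,
                    fold = fold, fisher_p = p,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Annotate sites with genomic features
#'
#' Assigns exactly one label per site with precedence
#' promoter > exon > intron > intergenic. The promoter window is taken from
#' the supplied promoter set (built as `[TSS - 2000, TSS + 500)` on the gene
#' strand by [promoter_windows()]); "intron" means inside a gene body but in
#' neither a promoter nor an exon.
#'
#' @param sites an [interval_set()] of sites (probes, peaks).
#' @param genes,promoters,exons `interval_set`s from the annotation bundle.
#' @return character vector of labels, one per site, in the site order.
#' @export
annotate_features <- function(sites, genes, promoters, exons) {
  known <- unique(c(genes$chrom, promoters$chrom, exons$chrom))
  bad <- setdiff(unique(sites$chrom), known)
  if (length(bad))
    stop_param("sites on chromosomes absent from the annotation: %s",
               paste(bad, collapse = ", "))
  gs <- to_granges(sites)
  in_prom <- GenomicRanges::countOverlaps(gs, to_granges(promoters),
                                          ignore.strand = TRUE) > 0
  in_exon <- GenomicRanges::countOverlaps(gs, to_granges(exons),
                                          ignore.strand = TRUE) > 0
  in_gene <- GenomicRanges::countOverlaps(gs, to_granges(genes),
                                          ignore.strand = TRUE) > 0
  ifelse(in_prom, "promoter",
         ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic")))
}

#' Classify sites by CpG density context
#'
#' `island` when inside a (merged) CpG island, `shore` within 2,000 bp of an
#' island edge, `shelf` within 2,000-4,000 bp, `open_sea` beyond. Distance is
#' the number of intervening bases between the site and the island.
#'
#' @param sites an [interval_set()].
#' @param islands CpG island `interval_set` (merged internally).
#' @return character vector of classes, one per site.
#' @export
cpg_density_class <- function(sites, islands) {
  gs <- to_granges(sites)
  gi <- GenomicRanges::reduce(to_granges(islands), ignore.strand = TRUE)
  cls <- rep("open_sea", nrow(sites))
  hit <- GenomicRanges::distanceToNearest(gs, gi, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit)
  d <- S4Vectors::mcols(hit)$distance
  inside <- GenomicRanges::countOverlaps(gs, gi, ignore.strand = TRUE) > 0
  cls[qh[d < 2000]] <- "shore"
  cls[qh[d >= 2000 & d < 4000]] <- "shelf"
  cls[inside] <- "island"
  cls
}

#' Expand sites to a fixed-width window around their midpoint
#'
#' Each site becomes an interval of `total_width` bp centred on its midpoint
#' (a 1-bp probe at position p with width 250 becomes `[p - 125, p + 125)`),
#' clipped at 0 and, when a genome is supplied, at the chromosome end.
#'
#' @param sites an [interval_set()].
#' @param total_width total window width in bp (>= 1).
#' @param genome optional data.frame (`chrom`, `length`) for right clipping.
#' @return the expanded `interval_set`.
#' @export
expand_window <- function(sites, total_width, genome = NULL) {
  if (!(is.numeric(total_width) && length(total_width) == 1L &&
        total_width >= 1))
    stop_param("total_width must be >= 1")
  mid <- floor((sites$start + sites$end) / 2)
  start <- pmax(0, mid - floor(total_width / 2))
  end <- start + total_width
  if (!is.null(genome)) {
    len <- genome$length[match(sites$chrom, genome$chrom)]
    end <- pmin(end, len)
  }
  keep_cols <- setdiff(names(sites), c("chrom", "start", "end"))
  do.call(interval_set,
          c(list(chrom = sites$chrom, start = start, end = end,
                 name = set_name(sites)),
            as.list(sites[, keep_cols, drop = FALSE])))
}

#' Pairs of intervals within a maximum gap, and the covered fraction
#'
#' Emits every pair `(a_i, b_j)` whose gap is at most `max_gap` bp (gap 0 for
#' overlapping or adjacent intervals) and the fraction of `a` elements with
#' at least one partner.
#'
#' @param a,b [interval_set()]s.
#' @param max_gap maximum separating gap in bp (>= 0).
#' @return list with `pairs` (data.frame of indices `a_idx`, `b_idx`) and
#'   `fraction` (fraction of `a` with a partner).
#' @export
proximity_join <- function(a, b, max_gap = 0) {
  if (!(is.numeric(max_gap) && length(max_gap) == 1L && max_gap >= 0))
    stop_param("max_gap must be non-negative")
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(to_granges(a), to_granges(b),
                                maxgap = max_gap, ignore.strand = TRUE))
  pairs <- data.frame(a_idx = S4Vectors::queryHits(ov),
                      b_idx = S4Vectors::subjectHits(ov))
  list(pairs = pairs,
       fraction = length(unique(pairs$a_idx)) / max(1L, nrow(a)))
}

#' Nearest gene per site
#'
#' Nearest gene body by bp distance (0 when the site is inside the gene);
#' ties broken by smaller gene start, then lexicographic gene id.
#'
#' @param sites an [interval_set()].
#' @param genes non-empty gene `interval_set` with an `id` column.
#' @return data.frame with `gene_id` and `distance` per site, in site order.
#' @export
nearest_gene <- function(sites, genes) {
  if (nrow(genes) == 0) stop_param("genes must be non-empty")
  gs <- to_granges(sites)
  gg <- to_granges(genes)
  near <- GenomicRanges::distanceToNearest(gs, gg, ignore.strand = TRUE)
  out <- data.frame(gene_id = rep(NA_character_, nrow(sites)),
                    distance = rep(NA_real_, nrow(sites)),
                    stringsAsFactors = FALSE)
  qh <- S4Vectors::queryHits(near)
  d <- S4Vectors::mcols(near)$distance
  if (!length(qh)) return(out)
  # distanceToNearest breaks ties arbitrarily; re-find every gene at the
  # minimum distance through a per-site window of that width, then apply
  # the deterministic (start, id) tie-break
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gs)[qh],
    IRanges::IRanges(start = pmax(1, GenomicRanges::start(gs)[qh] - d - 1),
                     end = GenomicRanges::end(gs)[qh] + d + 1))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(win, gg, ignore.strand = TRUE))
  cand <- data.frame(site = qh[S4Vectors::queryHits(ov)],
                     gene = S4Vectors::subjectHits(ov))
  cand$gap <- pmax(0,
                   pmax(genes$start[cand$gene] - sites$end[cand$site],
                        sites$start[cand$site] - genes$end[cand$gene]))
  cand <- cand[cand$gap == d[match(cand$site, qh)], , drop = FALSE]
  cand$gstart <- genes$start[cand$gene]
  cand$gid <- genes$id[cand$gene]
  cand <- cand[order(cand$site, cand$gstart, cand$gid), , drop = FALSE]
  cand <- cand[!duplicated(cand$site), , drop = FALSE]
  out$gene_id[cand$site] <- cand$gid
  out$distance[cand$site] <- cand$gap
  out
}
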