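# ChIP peak filtering, replicate consensus, count normalization and
# differential-binding calls.

#' Filter peak calls by width, q-value and fold-change from input
#'
#' Keeps peaks with width strictly below `max_width`, q-value strictly below
#' `q_max` and fold-change from input strictly above `min_fold` (the
#' inequalities as printed: `< 1.5 kb`, `q < 0.01`, `fold > 5`). Order is
#' preserved and the filter is idempotent.
#'
#' @param peaks an [interval_set()] with `q_value` and `fold_from_input`.
#' @param max_width maximum peak width in bp (exclusive; default 1500).
#' @param q_max q-value cutoff (exclusive; default 0.01).
#' @param min_fold fold-change-from-input cutoff (exclusive; default 5).
#' @return the filtered `interval_set`.
#' @export
filter_peaks <- function(peaks, max_width = 1500, q_max = 0.01, min_fold = 5) {
  check_positive(max_width, "max_width")
  check_positive(q_max, "q_max")
  check_positive(min_fold, "min_fold")
  stopifnot(all(c("q_value", "fold_from_input") %in% names(peaks)))
  width <- peaks$end - peaks$start
  keep <- width < max_width & peaks$q_value < q_max &
    peaks$fold_from_input > min_fold
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(peaks), set_name = set_name(peaks))
}

#' Reproducible consensus peaks from two replicates
#'
#' Replicate-consistency stand-in for IDR thresholding: peak pairs whose
#' reciprocal overlap is at least `min_reciprocal_overlap` in both directions
#' are matched greedily by descending fold-change from input, each peak used
#' at most once; every matched pair contributes its spanning union as a
#' consensus interval.
#'
#' @param rep_a,rep_b filtered peak [interval_set()]s with `fold_from_input`.
#' @param min_reciprocal_overlap minimum overlap fraction of each peak in
#'   `(0, 1]` (default 0.5).
#' @return consensus `interval_set`.
#' @export
reproducible_peaks <- function(rep_a, rep_b, min_reciprocal_overlap = 0.5) {
  check_fraction(min_reciprocal_overlap, "min_reciprocal_overlap",
                 open_left = TRUE)
  empty <- interval_set(character(0), numeric(0), numeric(0),
                        name = "consensus")
  if (nrow(rep_a) == 0 || nrow(rep_b) == 0) return(empty)
  ga <- to_granges(rep_a); gb <- to_granges(rep_b)
  ov <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  inter <- pmin(rep_a$end[qa], rep_b$end[qb]) -
    pmax(rep_a$start[qa], rep_b$start[qb])
  wa <- rep_a$end[qa] - rep_a$start[qa]
  wb <- rep_b$end[qb] - rep_b$start[qb]
  ok <- inter / wa >= min_reciprocal_overlap &
    inter / wb >= min_reciprocal_overlap
  qa <- qa[ok]; qb <- qb[ok]
  if (!length(qa)) return(empty)
  # greedy one-to-one matching by descending pair strength
  strength <- pmin(rep_a$fold_from_input[qa], rep_b$fold_from_input[qb])
  ord <- order(-strength, qa, qb)
  used_a <- logical(nrow(rep_a)); used_b <- logical(nrow(rep_b))
  keep <- logical(length(ord))
  for (i in ord) {
    if (!used_a[qa[i]] && !used_b[qb[i]]) {
      keep[i] <- TRUE
      used_a[qa[i]] <- TRUE
      used_b[qb[i]] <- TRUE
    }
  }
  qa <- qa[keep]; qb <- qb[keep]
  sort_intervals(interval_set(rep_a$chrom[qa],
                              pmin(rep_a$start[qa], rep_b$start[qb]),
                              pmax(rep_a$end[qa], rep_b$end[qb]),
                              name = "consensus"))
}

#' Median-library normalized log2 counts
#'
#' `log2(1 + count * median(lib) / lib)`: counts scaled to the median library
#' size with a pseudocount of 1. Monotone in the raw count within a sample.
#'
#' @param cset a [count_set()].
#' @return numeric matrix of normalized log2 counts.
#' @export
normalize_counts <- function(cset) {
  if (any(cset$lib_size <= 0)) stop_param("library sizes must be positive")
  sf <- median(cset$lib_size) / cset$lib_size
  log2(1 + sweep(cset$counts, 2, sf, "*"))
}

#' Call differentially bound regions
#'
#' Per-region Welch t-test on median-library normalized log2 counts between
#' two groups, with a variance floor at the 10th percentile of per-region
#' pooled variances (guarding the low-replicate designs typical of ChIP),
#' BH-FDR across regions, and joint FDR + |log2FC| calling.
#'
#' @param cset a [count_set()] of region counts.
#' @param groups length-2 character vector `c(test, reference)` of treatment
#'   labels; log2FC is test minus reference.
#' @param fdr_max,lfc_min calling thresholds (defaults 0.05 and 1).
#' @param var_floor_quantile quantile of pooled variances used as the floor
#'   (default 0.10).
#' @return data.frame of class `db_table`: `unit_id` (+ coordinates when
#'   present), `mean_log2_test`, `mean_log2_ref`, `log2_fc`, `p`, `fdr`,
#'   `called`, `direction` (`gain`/`loss`).
#' @export
call_differential_binding <- function(cset, groups = c("E2D", "CTR"),
                                      fdr_max = 0.05, lfc_min = 1.0,
                                      var_floor_quantile = 0.10) {
  check_fraction(fdr_max, "fdr_max", open_left = TRUE, open_right = TRUE)
  check_positive(lfc_min, "lfc_min")
  idx1 <- which(cset$samples$treatment == groups[1])
  idx2 <- which(cset$samples$treatment == groups[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop_param("each group needs >= 2 samples (got %d and %d)",
               length(idx1), length(idx2))
  Y <- normalize_counts(cset)
  y1 <- Y[, idx1, drop = FALSE]; y2 <- Y[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  floor_v <- quantile(pooled, var_floor_quantile, names = FALSE)
  v1 <- pmax(v1, floor_v); v2 <- pmax(v2, floor_v)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  fdr <- p.adjust(p, method = "BH")
  lfc <- m1 - m2
  called <- fdr < fdr_max & abs(lfc) > lfc_min
  out <- data.frame(unit_id = cset$units$unit_id, stringsAsFactors = FALSE)
  for (col in intersect(c("chrom", "start", "end"), names(cset$units)))
    out[[col]] <- cset$units[[col]]
  out$mean_log2_test <- m1
  out$mean_log2_ref <- m2
  out$log2_fc <- lfc
  out$p <- unname(p)
  out$fdr <- unname(fdr)
  out$called <- unname(called)
  out$direction <- ifelse(lfc < 0, "loss", "gain")
  out$direction[!called] <- NA_character_
  class(out) <- c("db_table", "data.frame")
  out
}
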