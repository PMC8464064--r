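# Genomic interval sets: 0-based half-open data.frames (BED convention) with
# a GRanges bridge for all overlap arithmetic. Probes are width-1 intervals.

#' Construct an interval set
#'
#' @param chrom,start,end vectors of chromosome names and 0-based half-open
#'   coordinates (`start < end`).
#' @param name label of the set.
#' @param ... further per-interval columns (e.g. `id`, `score`, `strand`,
#'   `q_value`, `fold_from_input`, `state`).
#' @return data.frame of class `interval_set`, in the supplied row order
#'   (use [sort_intervals()] for coordinate order).
#' @export
interval_set <- function(chrom, start, end, name = "intervals", ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop_param("chrom, start, end must have equal length")
  if (any(start < 0)) stop_param("interval starts must be non-negative")
  if (any(start >= end)) stop_param("intervals must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"), set_name = name)
}

#' Sort an interval set by (chrom, start, end)
#' @param x an `interval_set`.
#' @return the sorted `interval_set`.
#' @export
sort_intervals <- function(x) {
  out <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(x), set_name = set_name(x))
}

set_name <- function(x) attr(x, "set_name") %||% "intervals"

`%||%` <- function(a, b) if (is.null(a)) b else a

# interval_set -> GRanges (1-based closed internally)
to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"   # BED uses "." for unstranded
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}

#' Write an interval set as BED
#'
#' BED6 when `id`/`score`/`strand` columns are present, BED3 otherwise.
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom,
                   start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE))
  if (any(c("id", "score", "strand") %in% names(x))) {
    df$name <- if ("id" %in% names(x)) x$id else "."
    df$score <- if ("score" %in% names(x)) x$score else 0
    df$strand <- if ("strand" %in% names(x)) x$strand else "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into an interval set
#' @param path BED file path.
#' @param name label for the set (defaults to the file name).
#' @return an `interval_set`.
#' @export
read_bed <- function(path, name = basename(path)) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 6) {
    interval_set(df[[1]], df[[2]], df[[3]], name = name,
                 id = as.character(df[[4]]), score = df[[5]],
                 strand = as.character(df[[6]]))
  } else {
    interval_set(df[[1]], df[[2]], df[[3]], name = name)
  }
}

#' Read a MACS-style narrowPeak file
#'
#' 10-column narrowPeak: chrom, start, end, name, score, strand, fold-change
#' from input, -log10(p), -log10(q), summit offset.
#' @param path narrowPeak file path.
#' @param name label for the set.
#' @return `interval_set` with `q_value`, `fold_from_input`, `summit` columns.
#' @export
read_narrowpeak <- function(path, name = basename(path)) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 10)
    stop_param("narrowPeak requires 10 columns, got %d", ncol(df))
  interval_set(df[[1]], df[[2]], df[[3]], name = name,
               id = as.character(df[[4]]), score = df[[5]],
               strand = as.character(df[[6]]),
               fold_from_input = df[[7]],
               q_value = 10^(-df[[9]]),
               summit = df[[10]])
}

#' Write peaks as narrowPeak
#' @param x `interval_set` with `fold_from_input` and `q_value` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  df <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("id" %in% names(x)) x$id else paste0("peak", seq_len(nrow(x))),
    score = if ("score" %in% names(x)) x$score else 0,
    strand = ".",
    signal = x$fold_from_input,
    p = -log10(pmax(x$q_value, 1e-300)),
    q = -log10(pmax(x$q_value, 1e-300)),
    summit = if ("summit" %in% names(x)) x$summit else -1
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Probe coordinates as width-1 intervals
#' @param probes data.frame with `probe_id`, `chrom`, `pos` columns (e.g. the
#'   `probes` slot of a [methylation_set()]).
#' @param name label for the set.
#' @return an [interval_set()] with the probe ids in the `id` column.
#' @export
probes_as_intervals <- function(probes, name = "probes") {
  interval_set(probes$chrom, probes$pos, probes$pos + 1, name = name,
               id = probes$probe_id)
}
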