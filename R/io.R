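# Plain-text readers/writers for the pipeline's tabular interchange formats.

#' Write a methylation set as beta-matrix and sample-sheet TSVs
#'
#' @param mset a [methylation_set()].
#' @param betas_path output TSV for the beta matrix (`probe_id`, `chrom`,
#'   `pos`, one column per sample).
#' @param samples_path output TSV for the sample sheet.
#' @return invisibly, the two paths.
#' @export
write_methylation <- function(mset, betas_path, samples_path) {
  df <- cbind(mset$probes[, c("probe_id", "chrom", "pos")],
              as.data.frame(mset$beta))
  write.table(df, betas_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mset$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(betas_path, samples_path))
}

#' Read a methylation set from beta-matrix and sample-sheet TSVs
#'
#' @param betas_path beta matrix TSV as written by [write_methylation()]
#'   (`chrom`/`pos` columns optional; absent coordinates are filled with
#'   placeholders).
#' @param samples_path sample sheet TSV.
#' @return a [methylation_set()] (without detection p-values).
#' @export
read_methylation <- function(betas_path, samples_path) {
  df <- read.delim(betas_path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  has_coord <- all(c("chrom", "pos") %in% names(df))
  probes <- data.frame(
    probe_id = as.character(df$probe_id),
    chrom = if (has_coord) df$chrom else "chrUn",
    pos = if (has_coord) df$pos else seq_len(nrow(df)) - 1,
    stringsAsFactors = FALSE)
  beta <- as.matrix(df[, samples$sample_id, drop = FALSE])
  methylation_set(beta, probes, samples)
}

#' Write a count set as TSVs
#' @param cset a [count_set()].
#' @param counts_path output TSV (`unit_id` (+ coordinates for regions), one
#'   column per sample).
#' @param samples_path output TSV for the sample sheet.
#' @return invisibly, the paths.
#' @export
write_counts <- function(cset, counts_path, samples_path) {
  df <- cbind(cset$units, as.data.frame(cset$counts))
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cset$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read a count set from TSVs
#' @param counts_path counts TSV as written by [write_counts()].
#' @param samples_path sample sheet TSV.
#' @param kind `"rna"` or `"chip"`.
#' @return a [count_set()] with library sizes set to column totals.
#' @export
read_counts <- function(counts_path, samples_path, kind = c("rna", "chip")) {
  kind <- match.arg(kind)
  df <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  unit_cols <- intersect(c("unit_id", "chrom", "start", "end"), names(df))
  count_set(as.matrix(df[, samples$sample_id, drop = FALSE]),
            df[, unit_cols, drop = FALSE], samples, kind = kind)
}

#' Write a result table (DMP/DB/DEG/persistence) as TSV
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
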