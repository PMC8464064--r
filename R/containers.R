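# Core data containers. These are deliberately light: validated lists with a
# matrix payload plus probe/unit and sample annotation, in the spirit of a
# minimal SummarizedExperiment for the handful of assays this pipeline needs.

#' Construct a methylation beta-value set
#'
#' @param beta numeric matrix of beta values (probes x samples), all in
#'   `[0, 1]`.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos` (0-based);
#'   one row per row of `beta`.
#' @param samples data.frame with columns `sample_id`, `treatment`,
#'   `timepoint`, `replicate`; one row per column of `beta`.
#' @param detection_p optional matrix of per probe x sample detection
#'   p-values, same dimensions as `beta`.
#' @return object of class `methylation_set`.
#' @export
methylation_set <- function(beta, probes, samples, detection_p = NULL) {
  beta <- as.matrix(beta)
  stopifnot(is.numeric(beta))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_param("beta values must lie in [0, 1]")
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chrom", "pos") %in% names(probes)),
            nrow(probes) == nrow(beta))
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "treatment", "timepoint") %in% names(samples)),
            nrow(samples) == ncol(beta))
  if (anyDuplicated(samples$sample_id))
    stop_param("sample ids must be unique")
  if (anyDuplicated(probes$probe_id))
    stop_param("probe ids must be unique (each probe maps to one coordinate)")
  dimnames(beta) <- list(probes$probe_id, samples$sample_id)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    stopifnot(all(dim(detection_p) == dim(beta)))
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(list(beta = beta, probes = probes, samples = samples,
                 detection_p = detection_p),
            class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat("methylation_set:", nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  tab <- table(x$samples$treatment, x$samples$timepoint)
  print(tab)
  invisible(x)
}

#' Subset a methylation set by probes and/or samples
#'
#' @param x a `methylation_set`.
#' @param probes probe ids or logical/integer index over probes.
#' @param samples sample ids or logical/integer index over samples.
#' @return the subset `methylation_set`.
#' @export
subset_methylation <- function(x, probes = NULL, samples = NULL) {
  pi <- seq_len(nrow(x$beta))
  si <- seq_len(ncol(x$beta))
  if (!is.null(probes)) {
    pi <- if (is.character(probes)) match(probes, x$probes$probe_id) else pi[probes]
    if (anyNA(pi)) stop_param("unknown probe ids in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id) else si[samples]
    if (anyNA(si)) stop_param("unknown sample ids in subset")
  }
  methylation_set(x$beta[pi, si, drop = FALSE],
                  x$probes[pi, , drop = FALSE],
                  x$samples[si, , drop = FALSE],
                  if (!is.null(x$detection_p)) x$detection_p[pi, si, drop = FALSE])
}

#' Construct a read-count set
#'
#' @param counts non-negative integer matrix (units x samples).
#' @param units data.frame with a `unit_id` column (genes or regions; regions
#'   may carry `chrom`, `start`, `end`).
#' @param samples sample sheet data.frame (`sample_id`, `treatment`,
#'   `timepoint`, `replicate`).
#' @param lib_size per-sample library sizes; defaults to column totals.
#' @param kind `"rna"` or `"chip"`.
#' @return object of class `count_set`.
#' @export
count_set <- function(counts, units, samples, lib_size = NULL,
                      kind = c("rna", "chip")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_param("counts must be non-negative integers")
  stopifnot(is.data.frame(units), "unit_id" %in% names(units),
            nrow(units) == nrow(counts))
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(counts))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop_param("library sizes must be positive")
  dimnames(counts) <- list(units$unit_id, samples$sample_id)
  names(lib_size) <- samples$sample_id
  structure(list(counts = counts, units = units, samples = samples,
                 lib_size = lib_size, kind = kind),
            class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat("count_set (", x$kind, "): ", nrow(x$counts), " units x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Subset a count set by samples
#' @param x a `count_set`.
#' @param samples sample ids or index.
#' @return the subset `count_set` (library sizes are carried over, not
#'   recomputed).
#' @export
subset_counts <- function(x, samples) {
  si <- if (is.character(samples)) match(samples, x$samples$sample_id)
        else seq_len(ncol(x$counts))[samples]
  if (anyNA(si)) stop_param("unknown sample ids in subset")
  count_set(x$counts[, si, drop = FALSE], x$units,
            x$samples[si, , drop = FALSE], x$lib_size[si], kind = x$kind)
}
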