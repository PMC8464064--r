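# Reversibility after re-stimulation: quartile-stratified recovery of
# hypermethylated positions and set-algebra persistence classification.

#' Quartile-stratified recovery of hypermethylated positions
#'
#' Bins the supplied hypermethylated probes into quartiles of the control
#' group-mean beta at the evaluated timepoint (ties at quartile boundaries
#' broken by probe id order), and reports the per-quartile mean beta of each
#' group along with the mean delta-beta of the deprived and re-stimulated
#' groups against control. Welch t-tests compare the per-probe E2D and ReSt
#' group means against CTR overall.
#'
#' @param mset a [methylation_set()] containing CTR, E2D and ReSt samples at
#'   `timepoint`.
#' @param hyper_dmp_ids probe ids of the hypermethylated positions (>= 4).
#' @param timepoint evaluated timepoint (default `"d14"`).
#' @param groups treatment labels `c(control, deprived, restimulated)`.
#' @return list of class `quartile_summary`: `by_quartile` (data.frame with
#'   per-quartile group means and delta-betas), `group_means`, `t_e2d_vs_ctr`
#'   and `t_rest_vs_ctr` p-values.
#' @export
quartile_recovery <- function(mset, hyper_dmp_ids, timepoint = "d14",
                              groups = c("CTR", "E2D", "ReSt")) {
  stopifnot(inherits(mset, "methylation_set"))
  missing_g <- setdiff(groups, unique(mset$samples$treatment))
  if (length(missing_g))
    stop_param("missing treatment group(s): %s", paste(missing_g, collapse = ", "))
  if (length(hyper_dmp_ids) < 4)
    stop_param("need at least 4 probes to form quartiles")
  if (!all(hyper_dmp_ids %in% mset$probes$probe_id))
    stop_param("some probe ids are absent from the matrix")

  sub <- subset_methylation(
    mset, probes = hyper_dmp_ids,
    samples = mset$samples$treatment %in% groups &
      mset$samples$timepoint == timepoint)
  gmean <- sapply(groups, function(g)
    rowMeans(sub$beta[, sub$samples$treatment == g, drop = FALSE]))

  # quartiles of the control baseline; stable probe_id order breaks ties
  ord <- order(gmean[, groups[1]], sub$probes$probe_id)
  n <- length(ord)
  qsize <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  quart <- integer(n)
  quart[ord] <- rep(1:4, times = qsize)

  by_q <- do.call(rbind, lapply(1:4, function(q) {
    idx <- quart == q
    means <- colMeans(gmean[idx, , drop = FALSE])
    data.frame(quartile = paste0("Q", q), n = sum(idx),
               mean_ctr = means[groups[1]], mean_e2d = means[groups[2]],
               mean_rest = means[groups[3]],
               delta_e2d_ctr = means[groups[2]] - means[groups[1]],
               delta_rest_ctr = means[groups[3]] - means[groups[1]],
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  out <- list(
    by_quartile = by_q,
    group_means = colMeans(gmean),
    t_e2d_vs_ctr = t.test(gmean[, groups[2]], gmean[, groups[1]])$p.value,
    t_rest_vs_ctr = t.test(gmean[, groups[3]], gmean[, groups[1]])$p.value
  )
  class(out) <- "quartile_summary"
  out
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat("quartile recovery summary\n")
  print(x$by_quartile, digits = 3)
  cat(sprintf("Welch t vs CTR: E2D p = %.3g, ReSt p = %.3g\n",
              x$t_e2d_vs_ctr, x$t_rest_vs_ctr))
  invisible(x)
}

#' Classify persistence of called units across contrasts
#'
#' Given the units called in the deprivation contrast (control vs deprived)
#' and in the re-stimulation contrast (control vs re-stimulated), assigns
#' each unit exactly one status: `retained` when called in both with the
#' same direction, `reversed` when called in the deprivation contrast only
#' (or with a flipped direction), `new` when called in the re-stimulation
#' contrast only.
#'
#' @param calls_dep,calls_rest data.frames with `unit_id` and `direction`
#'   columns (e.g. the called subset of a `dmp_table`, `db_table` or
#'   `deg_table`, using their `probe_id`/`unit_id` as `unit_id`).
#' @return data.frame of class `persistence_table` with `unit_id`, `status`,
#'   `direction_dep`, `direction_rest`; the summary counts are attached as
#'   the `counts` attribute.
#' @export
classify_persistence <- function(calls_dep, calls_rest) {
  norm <- function(x, what) {
    if (is.null(x) || nrow(x) == 0)
      return(data.frame(unit_id = character(0), direction = character(0),
                        stringsAsFactors = FALSE))
    id_col <- intersect(c("unit_id", "probe_id"), names(x))[1]
    if (is.na(id_col)) stop_param("%s lacks a unit_id/probe_id column", what)
    if (!"direction" %in% names(x))
      stop_param("%s lacks a direction column", what)
    out <- data.frame(unit_id = as.character(x[[id_col]]),
                      direction = as.character(x$direction),
                      stringsAsFactors = FALSE)
    if (anyNA(out$direction))
      stop_param("direction missing for called units in %s", what)
    out
  }
  dep <- norm(calls_dep, "calls_dep")
  rest <- norm(calls_rest, "calls_rest")
  ids <- union(dep$unit_id, rest$unit_id)
  dir_dep <- dep$direction[match(ids, dep$unit_id)]
  dir_rest <- rest$direction[match(ids, rest$unit_id)]
  status <- ifelse(
    !is.na(dir_dep) & !is.na(dir_rest),
    ifelse(dir_dep == dir_rest, "retained", "reversed"),
    ifelse(!is.na(dir_dep), "reversed", "new"))
  out <- data.frame(unit_id = ids, status = status,
                    direction_dep = dir_dep, direction_rest = dir_rest,
                    stringsAsFactors = FALSE)
  out <- out[order(out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(reversed = sum(status == "reversed"),
                           retained = sum(status == "retained"),
                           new = sum(status == "new"))
  class(out) <- c("persistence_table", "data.frame")
  out
}

#' Combine persistence calls across assays
#'
#' @param dmp,db,deg `persistence_table`s (any may be NULL or empty).
#' @return data.frame with `assay`, `unit_id`, `status`, deterministically
#'   ordered by assay then unit id.
#' @export
recovery_report <- function(dmp = NULL, db = NULL, deg = NULL) {
  piece <- function(x, assay) {
    if (is.null(x) || nrow(x) == 0)
      return(data.frame(assay = character(0), unit_id = character(0),
                        status = character(0), stringsAsFactors = FALSE))
    data.frame(assay = assay, unit_id = x$unit_id, status = x$status,
               stringsAsFactors = FALSE)
  }
  out <- rbind(piece(dmp, "methylation"), piece(db, "h3k27ac"),
               piece(deg, "expression"))
  out <- out[order(out$assay, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
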