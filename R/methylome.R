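# Differential methylation: per-probe ordinary least squares on M-values with
# a treatment term adjusted for timepoint, BH-FDR across probes, joint
# FDR + delta-beta calling, and a treatment-label permutation null.

#' Logit (M-value) transform of beta values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta to `[eps, 1 - eps]` so
#' boundary values stay finite. Strictly increasing in beta.
#'
#' @param beta numeric vector/matrix of methylation fractions in `[0, 1]`.
#' @param eps clipping constant (default `1e-6`).
#' @return M-values with the same shape as `beta`.
#' @export
#' @examples
#' m_transform(c(0.5, 0.8)) # 0 and 2
m_transform <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_param("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Remove probes failing the detection p-value filter
#'
#' A probe is dropped when its detection p-value is at or above the threshold
#' in any sample (`mode = "any"`, the default strict reading) or in all
#' samples (`mode = "all"`). A matrix without detection p-values passes
#' through unchanged with a notice.
#'
#' @param mset a [methylation_set()].
#' @param detection_threshold detection p-value cutoff in `(0, 1]`
#'   (default 0.01).
#' @param mode `"any"` or `"all"` — how many samples must fail.
#' @return the filtered `methylation_set`, probe order preserved.
#' @export
filter_probes <- function(mset, detection_threshold = 0.01,
                          mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!(is.numeric(detection_threshold) && length(detection_threshold) == 1L &&
        detection_threshold > 0 && detection_threshold <= 1))
    stop_param("detection_threshold must lie in (0, 1]")
  if (is.null(mset$detection_p)) {
    message("no detection p-values present; probes passed through unfiltered")
    return(mset)
  }
  fail <- mset$detection_p >= detection_threshold
  drop <- if (mode == "any") rowSums(fail) > 0 else rowSums(fail) == ncol(fail)
  subset_methylation(mset, probes = !drop)
}

#' Fit the per-probe treatment model on M-values
#'
#' Ordinary least squares of M-values on a treatment indicator plus timepoint
#' factors, per probe, with a two-sided t-test on the treatment coefficient
#' and BH-FDR across all tested probes. Probes with zero residual variance
#' are flagged and excluded from testing. Delta-beta effect sizes are
#' computed on the beta scale as the difference of treatment group means,
#' pooled over the timepoints shared by both treatments (so the d0
#' control-only samples inform the time adjustment but not the effect size),
#' and also per shared timepoint.
#'
#' @param mset a [methylation_set()].
#' @param contrast length-2 character vector `c(test, reference)` of
#'   treatment labels; the coefficient is test minus reference.
#' @param adjust_timepoint include timepoint as a categorical covariate.
#' @return a `dmp_table` data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `m_effect`, `delta_beta_pooled`, one `delta_beta_<tp>` column per shared
#'   timepoint, `p`, `fdr`, `zero_variance`.
#' @export
fit_treatment_model <- function(mset, contrast = c("E2D", "CTR"),
                                adjust_timepoint = TRUE) {
  stopifnot(inherits(mset, "methylation_set"), length(contrast) == 2L)
  keep <- mset$samples$treatment %in% contrast
  if (!any(keep)) stop_param("no samples match the contrast")
  sub <- subset_methylation(mset, samples = keep)
  smp <- sub$samples
  n_per <- table(factor(smp$treatment, levels = contrast))
  if (any(n_per < 2))
    stop_param("need >= 2 samples per treatment (got %s)",
               paste(n_per, collapse = "/"))

  treat <- as.numeric(smp$treatment == contrast[1])
  X <- cbind(intercept = 1, treatment = treat)
  if (adjust_timepoint) {
    tps <- unique(smp$timepoint)
    if (length(tps) > 1) {
      tp <- factor(smp$timepoint, levels = tps)
      tp_mat <- stats::model.matrix(~ tp)[, -1, drop = FALSE]
      colnames(tp_mat) <- paste0("timepoint_", tps[-1])
      X <- cbind(X, tp_mat)
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])]
    stop_param("design matrix is rank-deficient; collinear columns: %s",
               paste(bad, collapse = ", "))
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 3)
    stop_param("fewer than 3 residual degrees of freedom (%d)", df_resid)

  M <- m_transform(sub$beta)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  B <- M %*% X %*% xtx_inv                   # probes x coefficients
  resid <- M - B %*% t(X)
  sigma2 <- rowSums(resid^2) / df_resid
  zero_var <- sigma2 < 1e-12
  se <- sqrt(sigma2 * xtx_inv["treatment", "treatment"])
  tstat <- B[, "treatment"] / se
  p <- 2 * pt(-abs(tstat), df_resid)
  p[zero_var] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[!zero_var] <- p.adjust(p[!zero_var], method = "BH")

  shared_tp <- intersect(smp$timepoint[smp$treatment == contrast[1]],
                         smp$timepoint[smp$treatment == contrast[2]])
  grp_mean <- function(treatment, tps) {
    cols <- smp$treatment == treatment & smp$timepoint %in% tps
    rowMeans(sub$beta[, cols, drop = FALSE])
  }
  delta_pooled <- grp_mean(contrast[1], shared_tp) -
    grp_mean(contrast[2], shared_tp)
  per_tp <- lapply(shared_tp, function(tp)
    grp_mean(contrast[1], tp) - grp_mean(contrast[2], tp))
  names(per_tp) <- paste0("delta_beta_", shared_tp)

  out <- data.frame(probe_id = sub$probes$probe_id,
                    chrom = sub$probes$chrom, pos = sub$probes$pos,
                    m_effect = unname(B[, "treatment"]),
                    delta_beta_pooled = unname(delta_pooled),
                    stringsAsFactors = FALSE)
  for (nm in names(per_tp)) out[[nm]] <- unname(per_tp[[nm]])
  out$p <- unname(p)
  out$fdr <- fdr
  out$zero_variance <- unname(zero_var)
  attr(out, "contrast") <- contrast
  attr(out, "df_resid") <- df_resid
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' Call differentially methylated positions
#'
#' A probe is called when `fdr < fdr_max` and `|delta_beta_pooled| >
#' delta_min` jointly hold; direction is `hyper` for positive and `hypo` for
#' negative pooled delta-beta.
#'
#' @param table a `dmp_table` from [fit_treatment_model()].
#' @param fdr_max BH-FDR threshold in `(0, 1)` (default 0.05).
#' @param delta_min delta-beta magnitude threshold in `(0, 1)` (default 0.10,
#'   the 10% cutoff).
#' @return the table with logical `called` and character `direction` columns.
#' @export
call_dmps <- function(table, fdr_max = 0.05, delta_min = 0.10) {
  check_fraction(fdr_max, "fdr_max", open_left = TRUE, open_right = TRUE)
  check_fraction(delta_min, "delta_min", open_left = TRUE, open_right = TRUE)
  called <- !is.na(table$fdr) & table$fdr < fdr_max &
    abs(table$delta_beta_pooled) > delta_min
  table$called <- called
  table$direction <- ifelse(table$delta_beta_pooled > 0, "hyper", "hypo")
  table$direction[!called] <- NA_character_
  table
}

#' Call probes on effect size alone
#'
#' Companion to [call_dmps()] used by the reversibility analysis: a probe is
#' called when `|delta_beta_pooled| > delta_min`, with no significance
#' requirement (the "signal comparable to the deprived group" reading of
#' persistence).
#'
#' @param table a `dmp_table`.
#' @param delta_min delta-beta magnitude threshold in `(0, 1)`.
#' @return the table with `called` and `direction` columns.
#' @export
call_effects <- function(table, delta_min = 0.10) {
  check_fraction(delta_min, "delta_min", open_left = TRUE, open_right = TRUE)
  called <- abs(table$delta_beta_pooled) > delta_min
  table$called <- called
  table$direction <- ifelse(table$delta_beta_pooled > 0, "hyper", "hypo")
  table$direction[!called] <- NA_character_
  table
}

#' Treatment-label permutation null for DMP calling
#'
#' Shuffles the treatment labels across the modelled samples (timepoint
#' labels stay put), refits the full model and re-calls DMPs, and records the
#' DMP count per shuffle. Labelings are sampled uniformly; sub-seeds derive
#' deterministically from `seed`.
#'
#' @param mset a [methylation_set()].
#' @param n_shuffles number of label shuffles (default 10).
#' @param seed master seed for the shuffle stream.
#' @param contrast treatments to model, as in [fit_treatment_model()].
#' @param fdr_max,delta_min calling thresholds, as in [call_dmps()].
#' @return integer vector of DMP counts, one per shuffle.
#' @export
permutation_null <- function(mset, n_shuffles = 10, seed = 1,
                             contrast = c("E2D", "CTR"),
                             fdr_max = 0.05, delta_min = 0.10) {
  if (!(is.numeric(n_shuffles) && length(n_shuffles) == 1L && n_shuffles >= 1))
    stop_param("n_shuffles must be >= 1")
  keep <- mset$samples$treatment %in% contrast
  sub <- subset_methylation(mset, samples = keep)
  vapply(seq_len(n_shuffles), function(i) {
    perm <- with_seed(derive_seed(seed, paste0("shuffle", i)),
                      sample(seq_len(nrow(sub$samples))))
    shuffled <- sub
    shuffled$samples$treatment <- sub$samples$treatment[perm]
    fit <- fit_treatment_model(shuffled, contrast = contrast)
    sum(call_dmps(fit, fdr_max, delta_min)$called)
  }, integer(1))
}
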