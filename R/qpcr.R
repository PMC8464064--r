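# Closed-form qPCR and oxidative-bisulfite quantification.

#' ChIP/hMeDIP percent of input
#'
#' `2^((Ct_input - log2(1/input_fraction)) - Ct_IP) * 100`: the input Ct is
#' first adjusted to a 100% input equivalent by the log2 of the dilution
#' factor — 6.64 cycles for a 1% input, 3.32 for a 10% input — and the
#' remaining cycle difference to the IP sample is converted to a percentage.
#' Exact `log2` constants are used; pass `dilution_constant` to reproduce
#' arithmetic done with the rounded printed constants.
#'
#' @param ct_input input-sample cycle threshold (> 0).
#' @param input_fraction fraction of chromatin in the input aliquot, in
#'   `(0, 1]` (e.g. 0.01 for a 1% input).
#' @param ct_ip IP-sample cycle threshold (> 0).
#' @param dilution_constant optional explicit cycle adjustment overriding
#'   `log2(1/input_fraction)`.
#' @return percent of input (vectorized).
#' @export
#' @examples
#' percent_input(25, 0.10, 23.68) # about 24.97%
percent_input <- function(ct_input, input_fraction, ct_ip,
                          dilution_constant = NULL) {
  if (any(ct_input <= 0) || any(ct_ip <= 0))
    stop_param("Ct values must be positive")
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop_param("input_fraction must lie in (0, 1]")
  k <- if (is.null(dilution_constant)) log2(1 / input_fraction)
       else dilution_constant
  2^((ct_input - k) - ct_ip) * 100
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-(dCt_sample - dCt_reference)` with
#' `dCt = Ct_target - Ct_housekeeping`; replicate Cts are averaged on the Ct
#' scale before differencing.
#'
#' @param ct_target,ct_housekeeping Ct replicates in the sample condition.
#' @param ct_target_ref,ct_housekeeping_ref Ct replicates in the reference
#'   condition.
#' @return fold-change relative to the reference condition.
#' @export
#' @examples
#' relative_expression(26, 20, 25, 20) # one extra cycle: fold 0.5
relative_expression <- function(ct_target, ct_housekeeping,
                                ct_target_ref, ct_housekeeping_ref) {
  vals <- list(ct_target, ct_housekeeping, ct_target_ref, ct_housekeeping_ref)
  if (any(vapply(vals, function(v) length(v) == 0 || any(v <= 0), logical(1))))
    stop_param("all Ct inputs must be non-empty and positive")
  ddct <- (mean(ct_target) - mean(ct_housekeeping)) -
    (mean(ct_target_ref) - mean(ct_housekeeping_ref))
  2^(-ddct)
}

#' siRNA knock-down efficiency
#'
#' Standard mode computes the percent knock-down from the remaining
#' expression fraction, `(1 - 2^-(dCt_siRNA - dCt_siNT)) * 100`. Printed
#' mode evaluates the published expression
#' `(100 - (2^-dCt_siRNA - 2^-dCt_siNT)) * 100` literally; it is preserved
#' for auditability but is dimensionally inconsistent (it is not a
#' percentage), which is why standard mode is the default.
#'
#' @param dct_sirna delta-Ct (target minus housekeeping) under the targeting
#'   siRNA.
#' @param dct_nt delta-Ct under the non-targeting control siRNA.
#' @param mode `"standard"` or `"printed"`.
#' @return percent knock-down (standard) or the literal printed value, with
#'   the mode in the `mode` attribute.
#' @export
#' @examples
#' kd_efficiency(3, 1) # remaining fraction 2^-2: 75% knock-down
kd_efficiency <- function(dct_sirna, dct_nt, mode = c("standard", "printed")) {
  mode <- match.arg(mode)
  out <- if (mode == "standard") {
    (1 - 2^(-(dct_sirna - dct_nt))) * 100
  } else {
    (100 - (2^(-dct_sirna) - 2^(-dct_nt))) * 100
  }
  attr(out, "mode") <- mode
  out
}

#' 5-hydroxymethylcytosine by oxidative-bisulfite subtraction
#'
#' `5hmC% = 5mC%_BS - 5mC%_oxBS`. Negative estimates are reported unclamped
#' and flagged `below_detection`.
#'
#' @param pct_bs percent methylation from standard bisulfite, in `[0, 100]`.
#' @param pct_oxbs percent methylation from oxidative bisulfite, in
#'   `[0, 100]`.
#' @param site_id optional site labels.
#' @return data.frame with `site_id`, `pct_5mc_bs`, `pct_5mc_oxbs`,
#'   `pct_5hmc`, `below_detection`.
#' @export
#' @examples
#' hydroxymethyl_subtract(60, 40) # 20% 5hmC
hydroxymethyl_subtract <- function(pct_bs, pct_oxbs,
                                   site_id = seq_along(pct_bs)) {
  if (any(pct_bs < 0 | pct_bs > 100) || any(pct_oxbs < 0 | pct_oxbs > 100))
    stop_param("percent methylation values must lie in [0, 100]")
  hmc <- pct_bs - pct_oxbs
  data.frame(site_id = as.character(site_id),
             pct_5mc_bs = pct_bs, pct_5mc_oxbs = pct_oxbs,
             pct_5hmc = hmc, below_detection = hmc < 0,
             stringsAsFactors = FALSE)
}

#' Read a long-format qPCR Ct table
#'
#' Expects columns `sample`, `condition`, `target`, `role` (one of `IP`,
#' `input`, `IgG`, `gene`, `housekeeping`), `ct` and optionally
#' `input_fraction` (required on `input` rows) and `replicate`.
#'
#' @param path TSV path.
#' @return validated data.frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "target", "role", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("Ct table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(df$ct <= 0)) stop_param("Ct values must be positive")
  bad_role <- setdiff(unique(df$role), c("IP", "input", "IgG", "gene",
                                         "housekeeping"))
  if (length(bad_role))
    stop_param("unknown role(s): %s", paste(bad_role, collapse = ", "))
  if ("input_fraction" %in% names(df)) {
    fr <- df$input_fraction[df$role == "input"]
    if (any(is.na(fr) | fr <= 0 | fr > 1))
      stop_param("input rows need input_fraction in (0, 1]")
  } else if (any(df$role == "input")) {
    stop_param("input rows require an input_fraction column")
  }
  class(df) <- c("ct_table", "data.frame")
  df
}
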