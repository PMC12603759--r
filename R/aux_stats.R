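# Self-contained auxiliary statistics: two-sample t-test sample size,
# 2^-ddCt relative quantification, and the cell-cycle proliferation ratio.

# power of the two-sample t-test with n per group, effect delta/sd
.t_test_power <- function(n, delta, sd, alpha,
                          alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  df <- 2 * (n - 1)
  ncp <- abs(delta) / sd * sqrt(n / 2)
  if (alternative == "two.sided") {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    1 - stats::pt(tcrit, df, ncp)
  }
}

#' Sample size for a two-sample t-test (equal group sizes)
#'
#' Smallest integer n per group such that a t-test with effect
#' `delta / sd` attains the target power, using the noncentral-t power
#' function. The minimum returned is 2 (the test needs at least 2
#' observations per group).
#'
#' @param delta mean difference between groups (any units; e.g. mm^3 tumor
#'   volume).
#' @param sd common standard deviation, same units.
#' @param alpha significance level (default 0.05, two-sided).
#' @param power target power (default 0.80).
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @param n_max search cap.
#' @return integer n per group.
#' @examples
#' sample_size_two_sample_t(delta = 400, sd = 125)  # 3 per group
#' @export
sample_size_two_sample_t <- function(delta, sd, alpha = 0.05, power = 0.80,
                                     alternative = c("two.sided",
                                                     "one.sided"),
                                     n_max = 1e6) {
  alternative <- match.arg(alternative)
  if (!is.finite(delta) || delta == 0) stop("delta must be non-zero")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  for (n in 2:n_max) {
    if (.t_test_power(n, delta, sd, alpha, alternative) >= power) {
      return(as.integer(n))
    }
  }
  stop("no n <= n_max attains the target power")
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated sample
#'   for the target and reference genes.
#' @param ct_target_control,ct_ref_control Ct values in the control sample.
#' @return fold change (1 = no change, 0.5 = halved expression).
#' @export
fold_change_ddct <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Proliferation ratio from cell-cycle phase counts
#'
#' Ratio of proliferating (S + G2) to non-proliferating (sub-G1 + G1)
#' cells from DNA-content gating counts.
#'
#' @param sub_g1,g1,s,g2 non-negative event counts.
#' @return `(s + g2) / (sub_g1 + g1)`.
#' @export
proliferation_ratio <- function(sub_g1, g1, s, g2) {
  counts <- c(sub_g1, g1, s, g2)
  if (any(counts < 0)) stop("phase counts must be non-negative")
  if (sub_g1 + g1 <= 0) stop("sub_g1 + g1 must be > 0")
  (s + g2) / (sub_g1 + g1)
}
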