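# Binary-outcome MR power (mRnd-style, Brion et al. approximation):
# forward power for a hypothesized odds ratio and the inverse
# smallest-detectable odds ratio at a target power.

check_power_inputs <- function(n_total, k, r2, alpha) {
  stopifnot(is_scalar_number(n_total), n_total > 0,
            is_scalar_number(k), k > 0, k < 1,
            is_scalar_number(r2), r2 > 0, r2 < 1,
            is_scalar_number(alpha), alpha > 0, alpha < 1)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' mRnd-style approximation: with an outcome case/control study of size
#' `n_total` and case fraction `k`, instruments explaining a fraction `r2`
#' of exposure variance, and a true odds ratio `or_` per unit exposure,
#' \deqn{power = \Phi\big(\sqrt{N R^2 K (1-K)}\,|\log OR| - z_{1-\alpha/2}\big)}
#' (two-sided test; `one_sided = TRUE` replaces the critical value with
#' `z_{1-alpha}`). At `or_ = 1` the two-sided power equals `alpha/2` (the
#' one remaining tail).
#'
#' @param n_total Outcome-study sample size (cases + controls).
#' @param k Case fraction in the outcome study, in (0, 1).
#' @param r2 Variance in the exposure explained by the instruments, (0, 1).
#' @param or_ Hypothesized odds ratio, > 0.
#' @param alpha Significance level (default 0.05).
#' @param one_sided Use a one-sided critical value (default FALSE).
#' @return Power in (0, 1).
#' @export
#' @examples
#' mr_power_binary(1683768, 38984 / 1683768, 0.0235, 1.094)
mr_power_binary <- function(n_total, k, r2, or_, alpha = 0.05,
                            one_sided = FALSE) {
  check_power_inputs(n_total, k, r2, alpha)
  stopifnot(is_scalar_number(or_), or_ > 0)
  crit <- if (one_sided) stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(n_total * r2 * k * (1 - k)) * abs(log(or_)) - crit)
}

#' Smallest detectable odds ratio at a target power
#'
#' Closed-form inversion of [mr_power_binary()]:
#' \deqn{\log OR = (z_{1-\alpha/2} + z_{power}) / \sqrt{N R^2 K (1-K)}}
#' Returns the OR above 1; the equally detectable OR below 1 is its
#' reciprocal. The round trip `mr_power_binary(detectable_or(...))`
#' recovers `target_power` to machine precision.
#'
#' @inheritParams mr_power_binary
#' @param target_power Desired power, in (0, 1) (default 0.8).
#' @return Odds ratio >= 1.
#' @export
#' @examples
#' detectable_or(1683768, 38984 / 1683768, 0.0235, target_power = 0.8)
detectable_or <- function(n_total, k, r2, target_power = 0.8, alpha = 0.05,
                          one_sided = FALSE) {
  check_power_inputs(n_total, k, r2, alpha)
  stopifnot(is_scalar_number(target_power), target_power > 0,
            target_power < 1)
  crit <- if (one_sided) stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  exp((crit + stats::qnorm(target_power)) /
        sqrt(n_total * r2 * k * (1 - k)))
}

#' Forward and inverse power summary for one analysis
#'
#' @inheritParams mr_power_binary
#' @param n_cases,n_controls Outcome case/control counts; `k` is computed
#'   as `n_cases / (n_cases + n_controls)`.
#' @param or_ Optional hypothesized OR for forward power.
#' @param target_power Target power for the detectable OR (default 0.8).
#' @return data.frame with `n_total`, `k`, `r2`, `alpha`, `or`, `power`,
#'   `target_power`, `detectable_or`.
#' @export
power_summary <- function(n_cases, n_controls, r2, or_ = NA_real_,
                          target_power = 0.8, alpha = 0.05,
                          one_sided = FALSE) {
  n_total <- n_cases + n_controls
  k <- n_cases / n_total
  pw <- if (is.na(or_)) NA_real_ else
    mr_power_binary(n_total, k, r2, or_, alpha, one_sided)
  data.frame(n_total = n_total, k = k, r2 = r2, alpha = alpha,
             or = or_, power = pw, target_power = target_power,
             detectable_or = detectable_or(n_total, k, r2, target_power,
                                           alpha, one_sided))
}
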