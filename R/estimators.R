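# Causal-effect estimators: per-SNP Wald ratios, inverse-variance weighted
# (IVW) meta-analysis, MR-Egger regression, weighted median, weighted mode.
# All operate on a harmonized InstrumentSet and return an MREstimate.

Z_975 <- stats::qnorm(0.975)

#' Construct an MR estimate
#'
#' @param method Method label.
#' @param beta Causal log-odds estimate.
#' @param se Its standard error.
#' @param n_snp Instrument count used.
#' @param df Degrees of freedom for a t-based p-value; `NULL` (default)
#'   uses the standard normal.
#' @param extra Named list of method-specific values.
#' @return Object of class `MREstimate` with fields `method`, `beta`, `se`,
#'   `or_`, `ci_low`, `ci_high`, `pval`, `n_snp`, `extra`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, df = NULL, extra = list()) {
  stopifnot(is_scalar_number(beta), is_scalar_number(se), se >= 0)
  ci <- to_odds_ratio(beta, se, df = df)
  structure(list(method = method, beta = beta, se = se,
                 or_ = ci$or_, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 pval = ci$pval, n_snp = as.integer(n_snp), extra = extra),
            class = "MREstimate")
}

#' @export
print.MREstimate <- function(x, ...) {
  cat(sprintf("%s (nSNP = %d): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$n_snp, x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.MREstimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, stringsAsFactors = FALSE)
}

#' Convert a log-odds estimate to an odds ratio with 95% CI and p-value
#'
#' @param beta Log-odds estimate.
#' @param se Standard error, `> 0` (a zero SE collapses the CI onto the OR
#'   and yields p = 0 for nonzero beta, p = 1 otherwise).
#' @param df Use a t distribution with `df` degrees of freedom for the
#'   p-value and CI multiplier; `NULL` uses the normal.
#' @return List `(or_, ci_low, ci_high, pval)`.
#' @export
to_odds_ratio <- function(beta, se, df = NULL) {
  mult <- if (is.null(df)) Z_975 else stats::qt(0.975, df)
  z <- if (se > 0) beta / se else sign(beta) * Inf
  pval <- if (se > 0) {
    if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  } else {
    as.numeric(beta == 0)
  }
  list(or_ = exp(beta), ci_low = exp(beta - mult * se),
       ci_high = exp(beta + mult * se), pval = pval)
}

# Wald ratios for every instrument in a set; zero exposure effects are a
# caller error (they make the ratio undefined).
wald_ratios <- function(set) {
  inst <- set$instruments
  if (any(inst$beta_exp == 0)) {
    stop("beta_exp = 0 for ",
         paste(inst$variant_id[inst$beta_exp == 0], collapse = ", "),
         ": Wald ratio undefined")
  }
  data.frame(variant_id = inst$variant_id,
             beta = inst$beta_out / inst$beta_exp,
             se = inst$se_out / abs(inst$beta_exp),
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimate
#'
#' `beta_j = beta_out / beta_exp`, `se_j = se_out / |beta_exp|` (first-order
#' delta method, exposure uncertainty ignored).
#'
#' @param beta_exp,se_exp Exposure effect and SE (`beta_exp != 0`).
#' @param beta_out,se_out Outcome effect and SE.
#' @return List `(beta, se)`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  stopifnot(is_scalar_number(beta_exp))
  if (beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined")
  list(beta = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effect meta-analysis of the per-SNP Wald ratios with weights
#' `1/se_j^2`, equivalent to weighted least squares of the outcome effects
#' on the exposure effects through the origin with weights `1/se_out^2`.
#' Under `random_effects = "multiplicative"` (default) the fixed-effect SE
#' is inflated by `sqrt(Q/df)` whenever Cochran's Q exceeds its degrees of
#' freedom (floor 1: the SE is never deflated). The p-value is two-sided
#' normal.
#'
#' @param set An `InstrumentSet`.
#' @param random_effects `"multiplicative"` or `"fixed"`.
#' @param min_snp Minimum instrument count (default 2; set 1 to allow the
#'   single-SNP case, which reduces exactly to the Wald ratio).
#' @return An [mr_estimate()] with `extra$q`, `extra$q_df`, `extra$q_pval`.
#' @export
mr_ivw <- function(set, random_effects = c("multiplicative", "fixed"),
                   min_snp = 2L) {
  random_effects <- match.arg(random_effects)
  n <- n_instruments(set)
  if (n < min_snp || n < 1L) {
    stop("IVW requires at least ", max(min_snp, 1L), " instruments, got ", n)
  }
  r <- wald_ratios(set)
  w <- 1 / r$se^2
  beta <- sum(w * r$beta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r$beta - beta)^2)
  df <- n - 1L
  scale <- 1
  if (random_effects == "multiplicative" && df > 0L && q > df) {
    scale <- sqrt(q / df)
  }
  mr_estimate("IVW", beta, se_fixed * scale, n,
              extra = list(q = q, q_df = df,
                           q_pval = if (df > 0L)
                             stats::pchisq(q, df, lower.tail = FALSE)
                           else NA_real_,
                           random_effects = random_effects,
                           se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, weights `1/se_out^2`. Inputs are first
#' re-oriented so that every exposure effect is non-negative (both betas of
#' a SNP flip sign together, which leaves Wald ratios unchanged). The slope
#' estimates the causal effect; the intercept indexes directional
#' pleiotropy. Standard errors use the weighted fit's residual standard
#' deviation bounded below by 1 (multiplicative over-dispersion only), and
#' p-values come from a t distribution with `n_snp - 2` degrees of freedom.
#'
#' @param set An `InstrumentSet` with at least 3 instruments.
#' @return An [mr_estimate()] with `extra$intercept`, `extra$intercept_se`,
#'   `extra$intercept_pval`, `extra$residual_scale`.
#' @export
mr_egger <- function(set) {
  n <- n_instruments(set)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments, got ", n)
  inst <- set$instruments
  flip <- sign(inst$beta_exp)
  flip[flip == 0] <- 1
  bx <- inst$beta_exp * flip
  by <- inst$beta_out * flip
  w <- 1 / inst$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- stats::coef(fit)
  df <- n - 2L
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / df)
  scale <- max(1, sigma)
  # unscaled covariance: (X' W X)^{-1}
  xwx <- crossprod(cbind(1, bx) * sqrt(w))
  vc <- solve(xwx) * scale^2
  se_slope <- sqrt(vc[2, 2])
  se_int <- sqrt(vc[1, 1])
  int <- unname(coefs[1])
  mr_estimate("MR_Egger", unname(coefs[2]), se_slope, n, df = df,
              extra = list(
                intercept = int, intercept_se = se_int,
                intercept_pval = 2 * stats::pt(-abs(int / se_int), df),
                residual_scale = scale))
}

# Weighted median of values x with non-negative weights w: order x, form
# cumulative weight midpoints s_j = sum_{k<j} w'_k + w'_j/2 on normalized
# weights, and linearly interpolate the x bracketing s = 0.5.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(x[1L])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  hi <- which(s >= 0.5)[1L]
  lo <- hi - 1L
  x[lo] + (0.5 - s[lo]) / (s[hi] - s[lo]) * (x[hi] - x[lo])
}

# Parametric bootstrap SE shared by the median and mode estimators:
# resample each SNP's exposure and outcome betas from normal laws centred
# on the observed values with the observed SEs, recompute the point
# estimate, and take the SD across replicates. Seeded via the package's
# derive_seed() contract (counter 1).
bootstrap_se <- function(set, estimator, n_boot, seed) {
  inst <- set$instruments
  n <- nrow(inst)
  set.seed(derive_seed(seed, 1))
  bx <- matrix(stats::rnorm(n_boot * n, mean = rep(inst$beta_exp,
                                                   each = n_boot),
                            sd = rep(inst$se_exp, each = n_boot)),
               nrow = n_boot)
  by <- matrix(stats::rnorm(n_boot * n, mean = rep(inst$beta_out,
                                                   each = n_boot),
                            sd = rep(inst$se_out, each = n_boot)),
               nrow = n_boot)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bxb <- bx[b, ]
    bxb[bxb == 0] <- .Machine$double.eps
    ratio <- by[b, ] / bxb
    se_ratio <- inst$se_out / abs(bxb)
    est[b] <- estimator(ratio, 1 / se_ratio^2)
  }
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' Median of the per-SNP Wald ratios under normalized inverse-variance
#' weights, linearly interpolated between the ratios bracketing cumulative
#' weight 0.5. Consistent when at least half of the total weight comes from
#' valid instruments. SE by seeded parametric bootstrap.
#'
#' @param set An `InstrumentSet` with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Root seed for the bootstrap (required).
#' @return An [mr_estimate()] with `extra$n_boot`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed) {
  n <- n_instruments(set)
  if (n < 3L) stop("weighted median requires at least 3 instruments, got ", n)
  stopifnot(is_scalar_number(seed))
  r <- wald_ratios(set)
  beta <- weighted_median_value(r$beta, 1 / r$se^2)
  se <- bootstrap_se(set, function(x, w) weighted_median_value(x, w),
                     n_boot, seed)
  mr_estimate("weighted_median", beta, se, n,
              extra = list(n_boot = n_boot, seed = seed))
}

# Mode of a weighted kernel density over the Wald ratios. Bandwidth is a
# Silverman-type rule on the ratio spread, scaled by bandwidth_factor.
weighted_mode_value <- function(x, w, bandwidth_factor = 1) {
  if (length(unique(x)) == 1L) return(x[1L])
  spread <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (spread <= 0) spread <- stats::sd(x)
  h <- bandwidth_factor * 0.9 * spread * length(x)^(-1 / 5)
  d <- stats::density(x, weights = w / sum(w), bw = h, n = 1024)
  d$x[which.max(d$y)]
}

#' Weighted-mode causal estimate
#'
#' Argmax of a normal-kernel density over the per-SNP Wald ratios with
#' inverse-variance weights; consistent when the largest homogeneous
#' cluster of instruments is valid. Bandwidth is `bandwidth_factor` times a
#' Silverman-type rule (`0.9 min(sd, IQR/1.349) n^{-1/5}`); the mode is
#' located on a fixed 1024-point grid. SE by the same seeded parametric
#' bootstrap as [mr_weighted_median()].
#'
#' @param set An `InstrumentSet` with at least 3 instruments.
#' @param bandwidth_factor Positive multiplier on the rule-of-thumb
#'   bandwidth (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Root seed for the bootstrap (required).
#' @return An [mr_estimate()] with `extra$n_boot`, `extra$bandwidth_factor`.
#' @export
mr_weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000L,
                             seed) {
  n <- n_instruments(set)
  if (n < 3L) stop("weighted mode requires at least 3 instruments, got ", n)
  stopifnot(is_scalar_number(seed), bandwidth_factor > 0)
  r <- wald_ratios(set)
  beta <- weighted_mode_value(r$beta, 1 / r$se^2, bandwidth_factor)
  se <- bootstrap_se(set,
                     function(x, w) weighted_mode_value(x, w,
                                                        bandwidth_factor),
                     n_boot, seed)
  mr_estimate("weighted_mode", beta, se, n,
              extra = list(n_boot = n_boot, seed = seed,
                           bandwidth_factor = bandwidth_factor))
}

#' Run all four MR estimators on one instrument set
#'
#' @param set An `InstrumentSet`.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Root seed.
#' @param methods Subset of
#'   `c("IVW", "weighted_median", "weighted_mode", "MR_Egger")`.
#' @return Named list of [mr_estimate()] objects.
#' @export
mr_all_methods <- function(set, n_boot = 1000L, seed,
                           methods = c("IVW", "weighted_median",
                                       "weighted_mode", "MR_Egger")) {
  out <- list()
  if ("IVW" %in% methods) out$IVW <- mr_ivw(set)
  if ("weighted_median" %in% methods) {
    out$weighted_median <- mr_weighted_median(set, n_boot,
                                              derive_seed(seed, 101))
  }
  if ("weighted_mode" %in% methods) {
    out$weighted_mode <- mr_weighted_mode(set, n_boot = n_boot,
                                          seed = derive_seed(seed, 102))
  }
  if ("MR_Egger" %in% methods) out$MR_Egger <- mr_egger(set)
  out
}
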