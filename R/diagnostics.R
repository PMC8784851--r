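# Heterogeneity and pleiotropy diagnostics: Cochran Q, Egger intercept,
# MR-PRESSO (global / outlier / distortion), leave-one-out, and the plain
# tables behind scatter, funnel and forest plots.

#' Cochran Q heterogeneity test over the per-SNP Wald ratios
#'
#' `Q = sum_j w_j (b_j - beta_ref)^2` with inverse-variance weights
#' `w_j = 1/se_j^2`, degrees of freedom `n_snp - 1`, p from the chi-square
#' upper tail. `beta_ref` defaults to the fixed-effect IVW estimate.
#'
#' @param set An `InstrumentSet` with at least 2 instruments.
#' @param beta_ref Reference log-odds effect; `NULL` recomputes fixed IVW.
#' @return List `(q, q_df, q_pval)`.
#' @export
cochran_q <- function(set, beta_ref = NULL) {
  n <- n_instruments(set)
  if (n < 2L) stop("Cochran Q requires at least 2 instruments, got ", n)
  r <- wald_ratios(set)
  w <- 1 / r$se^2
  if (is.null(beta_ref)) beta_ref <- sum(w * r$beta) / sum(w)
  q <- sum(w * (r$beta - beta_ref)^2)
  df <- n - 1L
  list(q = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Intercept, SE and two-sided t(n-2) p-value from the [mr_egger()] fit. A
#' small p indicates directional horizontal pleiotropy driving the causal
#' estimate.
#'
#' @param set An `InstrumentSet` with at least 3 instruments.
#' @return List `(intercept, se, pval)`.
#' @export
egger_intercept_test <- function(set) {
  fit <- mr_egger(set)
  list(intercept = fit$extra$intercept, se = fit$extra$intercept_se,
       pval = fit$extra$intercept_pval)
}

# Leave-one-out fixed-effect slopes of the through-origin weighted
# regression of beta_out on beta_exp with weights 1/se_out^2 (identical to
# IVW on the Wald ratios). Returns the vector beta_loo(-j) for every j.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based test for horizontal pleiotropy. For each SNP `j` the
#' causal slope is refit without `j` (fixed-effect IVW) and the weighted
#' squared residual `w_j (b_out_j - beta_(-j) b_exp_j)^2` is formed; the
#' observed residual sum of squares (RSS) is compared with a null
#' distribution built from `n_sim` parametric simulations in which each
#' outcome beta is redrawn from a normal law centred on its leave-one-out
#' fitted value with its own SE, and the full leave-one-out RSS is
#' recomputed on the simulated data. The global p is the empirical
#' upper-tail proportion; an exceedance count of zero is reported as
#' `< 1/n_sim` and stored numerically as `1/(2 n_sim)`. Each SNP's observed
#' weighted residual is likewise compared with its simulated residuals and
#' the per-SNP p is Bonferroni-adjusted by `n_snp`; SNPs below
#' `outlier_alpha` are flagged as outliers. When outliers are flagged, a
#' distortion test compares the all-SNP IVW slope with the outlier-removed
#' slope against a simulated distortion distribution obtained by removing
#' random same-size subsets of non-outlier SNPs.
#'
#' Randomness follows the package seed contract: one root seed; simulation
#' draws come from stream `derive_seed(seed, 1)` as a single
#' `n_sim x n_snp` column-major normal matrix, the distortion resampling
#' from stream `derive_seed(seed, 2)`, so results do not depend on
#' iteration order.
#'
#' @param set An `InstrumentSet` with at least 4 instruments.
#' @param n_sim Number of parametric simulations (>= 100; default 1000).
#' @param seed Root seed (required).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @return List with `global_rss`, `global_p`, `global_p_label`, `outliers`
#'   (data.frame `variant_id`, `pval`), `distortion_p` (`NA` when no
#'   outliers), `distortion_coef`, `n_sim`.
#' @export
mr_presso <- function(set, n_sim = 1000L, seed, outlier_alpha = 0.05) {
  n <- n_instruments(set)
  if (n < 4L) stop("MR-PRESSO requires at least 4 instruments, got ", n)
  if (n_sim < 100L) stop("n_sim must be at least 100")
  stopifnot(is_scalar_number(seed))
  inst <- set$instruments
  bx <- inst$beta_exp
  by <- inst$beta_out
  se_out <- inst$se_out
  w <- 1 / se_out^2

  slopes_obs <- loo_slopes(bx, by, w)
  resid_obs <- w * (by - slopes_obs * bx)^2
  rss_obs <- sum(resid_obs)

  # Null draws: by*_ij ~ N(beta_(-j) * bx_j, se_out_j), one matrix draw.
  set.seed(derive_seed(seed, 1))
  mu <- slopes_obs * bx
  bysim <- matrix(stats::rnorm(n_sim * n), nrow = n_sim, ncol = n)
  bysim <- sweep(bysim, 2, se_out, `*`)
  bysim <- sweep(bysim, 2, mu, `+`)

  # Leave-one-out slopes on each simulated dataset, vectorised over sims.
  sxx <- sum(w * bx^2)
  wx <- w * bx                                  # length n
  sxy_sim <- bysim %*% wx                       # n_sim x 1
  slope_sim <- (matrix(sxy_sim, n_sim, n) -
                  sweep(bysim, 2, wx, `*`)) /
    matrix(sxx - w * bx^2, n_sim, n, byrow = TRUE)
  resid_sim <- sweep((bysim - slope_sim *
                        matrix(bx, n_sim, n, byrow = TRUE))^2, 2, w, `*`)
  rss_sim <- rowSums(resid_sim)

  exceed <- sum(rss_sim >= rss_obs)
  global_p <- if (exceed == 0L) 1 / (2 * n_sim) else exceed / n_sim
  global_label <- if (exceed == 0L) sprintf("< %.3g", 1 / n_sim)
  else sprintf("%.4g", exceed / n_sim)

  pj <- colMeans(sweep(resid_sim, 2, resid_obs, `>=`))
  pj_adj <- pmin(1, pj * n)
  flagged <- which(pj_adj < outlier_alpha)
  outliers <- data.frame(variant_id = inst$variant_id[flagged],
                         pval = pj_adj[flagged], stringsAsFactors = FALSE)

  distortion_p <- NA_real_
  distortion_coef <- NA_real_
  if (length(flagged) > 0L && length(flagged) < n - 1L) {
    keep <- setdiff(seq_len(n), flagged)
    slope_all <- sum(w * bx * by) / sum(w * bx^2)
    slope_clean <- sum(w[keep] * bx[keep] * by[keep]) /
      sum(w[keep] * bx[keep]^2)
    distortion_coef <- 100 * (slope_all - slope_clean) / abs(slope_clean)
    set.seed(derive_seed(seed, 2))
    d_sim <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
      fake_out <- sample(keep, length(flagged), replace = TRUE)
      sub <- setdiff(keep, fake_out)
      slope_sub <- sum(w[sub] * bx[sub] * by[sub]) /
        sum(w[sub] * bx[sub]^2)
      d_sim[i] <- 100 * (slope_all - slope_sub) / abs(slope_sub)
    }
    distortion_p <- mean(abs(d_sim) >= abs(distortion_coef))
    if (distortion_p == 0) distortion_p <- 1 / (2 * n_sim)
  }

  list(global_rss = rss_obs, global_p = global_p,
       global_p_label = global_label, outliers = outliers,
       distortion_p = distortion_p, distortion_coef = distortion_coef,
       n_sim = n_sim)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate with each instrument removed in turn, to expose
#' single influential SNPs.
#'
#' @param set An `InstrumentSet` with at least 3 instruments.
#' @param random_effects Passed to [mr_ivw()].
#' @return data.frame with one row per dropped SNP: `dropped`, `beta`,
#'   `se`, `pval`, `n_snp`.
#' @export
leave_one_out <- function(set,
                          random_effects = c("multiplicative", "fixed")) {
  random_effects <- match.arg(random_effects)
  n <- n_instruments(set)
  if (n < 3L) stop("leave-one-out requires at least 3 instruments, got ", n)
  rows <- lapply(seq_len(n), function(j) {
    sub <- instrument_set(set$instruments[-j, , drop = FALSE])
    fit <- mr_ivw(sub, random_effects = random_effects)
    data.frame(dropped = set$instruments$variant_id[j], beta = fit$beta,
               se = fit$se, pval = fit$pval, n_snp = fit$n_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full diagnostics report for one exposure-outcome pair
#'
#' Bundles Cochran Q, the Egger intercept test, MR-PRESSO and the
#' leave-one-out table.
#'
#' @param set An `InstrumentSet`.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Root seed.
#' @param outlier_alpha MR-PRESSO outlier significance level.
#' @return Object of class `DiagnosticsReport`: list with `q`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `presso` and `loo`.
#' @export
mr_diagnostics <- function(set, n_sim = 1000L, seed, outlier_alpha = 0.05) {
  q <- cochran_q(set)
  eg <- egger_intercept_test(set)
  presso <- mr_presso(set, n_sim = n_sim, seed = derive_seed(seed, 201),
                      outlier_alpha = outlier_alpha)
  loo <- leave_one_out(set)
  structure(list(q = q$q, q_df = q$q_df, q_pval = q$q_pval,
                 egger_intercept = eg$intercept,
                 egger_intercept_se = eg$se,
                 egger_intercept_pval = eg$pval,
                 presso = presso, loo = loo),
            class = "DiagnosticsReport")
}

#' @export
print.DiagnosticsReport <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f (df %d), p = %.3g\n", x$q, x$q_df, x$q_pval))
  cat(sprintf("Egger intercept = %.4f, p = %.3g\n", x$egger_intercept,
              x$egger_intercept_pval))
  cat(sprintf("MR-PRESSO global p %s; %d outlier(s)\n",
              x$presso$global_p_label, nrow(x$presso$outliers)))
  invisible(x)
}

#' Plain-table data behind the standard MR plots
#'
#' Produces the scatter, funnel and forest tables as data.frames suitable
#' for writing as delimited files or plotting with any graphics system.
#'
#' @param set An `InstrumentSet`.
#' @param estimates List of [mr_estimate()] objects (non-empty).
#' @return List with `scatter` (per-SNP effects and SEs plus one fitted
#'   line per method), `funnel` (Wald ratio vs precision with the IVW
#'   vertical), `forest` (per-SNP ratios with 95% CIs plus one summary row
#'   per method).
#' @export
plot_data <- function(set, estimates) {
  stopifnot(length(estimates) > 0L)
  inst <- set$instruments
  r <- wald_ratios(set)
  lines <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, slope = e$beta,
               intercept = e$extra$intercept %||% 0,
               stringsAsFactors = FALSE)
  }))
  scatter <- list(
    points = data.frame(variant_id = inst$variant_id,
                        beta_exp = inst$beta_exp, se_exp = inst$se_exp,
                        beta_out = inst$beta_out, se_out = inst$se_out,
                        stringsAsFactors = FALSE),
    lines = lines)
  ivw_beta <- NA_real_
  for (e in estimates) if (e$method == "IVW") ivw_beta <- e$beta
  funnel <- data.frame(variant_id = r$variant_id, beta = r$beta,
                       precision = 1 / r$se, ivw_beta = ivw_beta,
                       stringsAsFactors = FALSE)
  per_snp <- data.frame(label = r$variant_id, beta = r$beta, se = r$se,
                        ci_low = r$beta - Z_975 * r$se,
                        ci_high = r$beta + Z_975 * r$se,
                        kind = "snp", stringsAsFactors = FALSE)
  summaries <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(label = e$method, beta = e$beta, se = e$se,
               ci_low = log(e$ci_low), ci_high = log(e$ci_high),
               kind = "summary", stringsAsFactors = FALSE)
  }))
  list(scatter = scatter, funnel = funnel,
       forest = rbind(per_snp, summaries))
}
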