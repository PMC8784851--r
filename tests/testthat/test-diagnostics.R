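test_that("Cochran Q matches hand arithmetic", {
  set <- ratio_set(c(0.2, 0.4), c(0.1, 0.1))  # weights 100, 100; IVW 0.3
  q <- cochran_q(set)
  expect_equal(q$q, 2.0)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(2, 1, lower.tail = FALSE))

  same <- ratio_set(rep(0.5, 3), rep(0.1, 3))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0)
  expect_equal(q0$q_pval, 1)
  expect_error(cochran_q(ratio_set(0.5, 0.1)), "at least 2")
})

test_that("Q decomposes exactly over a leave-one-out split", {
  sim <- simulate_two_sample(calib_config(seed = 31, n_snp = 25,
                                          beta_causal = 0.1,
                                          pleiotropy = list(
                                            type = "balanced", sd = 0.005)))
  set <- set_from_sim(sim)
  r <- wald_ratios(set)
  w <- 1 / r$se^2
  beta_full <- sum(w * r$beta) / sum(w)
  q_full <- cochran_q(set)$q
  for (j in c(1, 7, 25)) {
    sub <- instrument_set(set$instruments[-j, , drop = FALSE])
    beta_loo <- mr_ivw(sub, random_effects = "fixed")$beta
    q_loo <- cochran_q(sub)$q
    rebuilt <- q_loo + sum(w[-j]) * (beta_loo - beta_full)^2 +
      w[j] * (r$beta[j] - beta_full)^2
    expect_equal(rebuilt, q_full, tolerance = 1e-10)
  }
})

test_that("Q p-values are uniform under a no-heterogeneity null", {
  pvals <- vapply(1:800, function(seed) {
    sim <- simulate_two_sample(calib_config(seed = seed, n_snp = 20))
    cochran_q(set_from_sim(sim))$q_pval
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Egger intercept test recovers a planted directional effect", {
  # exact-line toy: intercept 0.01 recovered exactly
  bx <- c(0.1, 0.2, 0.3)
  set <- toy_set(bx, rep(0.01, 3), 0.01 + 0.2 * bx, c(0.03, 0.05, 0.07))
  eg <- egger_intercept_test(set)
  expect_equal(eg$intercept, 0.01, tolerance = 1e-10)

  # directional pleiotropy mean 0.02: CI covers the truth in most sims
  covered <- vapply(1:100, function(seed) {
    sim <- simulate_two_sample(calib_config(
      seed = seed, n_snp = 100, beta_causal = 0.1,
      pleiotropy = list(type = "directional", mean = 0.02, sd = 0.003)))
    eg <- egger_intercept_test(set_from_sim(sim))
    crit <- qt(0.975, 98)
    eg$intercept - crit * eg$se <= 0.02 &&
      0.02 <= eg$intercept + crit * eg$se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("Egger intercept rejection rate is near nominal under the null", {
  rej <- vapply(1:400, function(seed) {
    sim <- simulate_two_sample(calib_config(seed = seed, n_snp = 50,
                                            beta_causal = 0.1))
    egger_intercept_test(set_from_sim(sim))$pval < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.10)
})

test_that("MR-PRESSO is seed-reproducible and matches a brute-force oracle", {
  sim <- simulate_two_sample(calib_config(seed = 55, n_snp = 4,
                                          beta_causal = 0.1))
  set <- set_from_sim(sim)
  res1 <- mr_presso(set, n_sim = 150, seed = 9)
  res2 <- mr_presso(set, n_sim = 150, seed = 9)
  expect_identical(res1, res2)

  # independent loop-based reimplementation under the same seed contract
  inst <- set$instruments
  bx <- inst$beta_exp; by <- inst$beta_out; so <- inst$se_out
  w <- 1 / so^2
  n <- 4L; n_sim <- 150L
  slope_wo <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)
  loo <- vapply(1:n, function(j) slope_wo(bx[-j], by[-j], w[-j]),
                numeric(1))
  resid_obs <- w * (by - loo * bx)^2
  set.seed(derive_seed(9, 1))
  draws <- matrix(rnorm(n_sim * n), nrow = n_sim, ncol = n)
  rss_sim <- numeric(n_sim)
  resid_sim <- matrix(0, n_sim, n)
  for (i in 1:n_sim) {
    bysim <- loo * bx + so * draws[i, ]
    loos <- vapply(1:n, function(j) slope_wo(bx[-j], bysim[-j], w[-j]),
                   numeric(1))
    resid_sim[i, ] <- w * (bysim - loos * bx)^2
    rss_sim[i] <- sum(resid_sim[i, ])
  }
  exceed <- sum(rss_sim >= sum(resid_obs))
  want_p <- if (exceed == 0) 1 / (2 * n_sim) else exceed / n_sim
  expect_identical(res1$global_p, want_p)
  want_pj <- pmin(1, colMeans(sweep(resid_sim, 2, resid_obs, ">=")) * n)
  flagged <- which(want_pj < 0.05)
  expect_identical(res1$outliers$variant_id, inst$variant_id[flagged])
})

test_that("MR-PRESSO flags a planted outlier and the distortion direction", {
  sim <- simulate_two_sample(calib_config(
    seed = 101, n_snp = 40, beta_causal = 0.2,
    outliers = data.frame(index = 13, displacement = 8)))
  set <- set_from_sim(sim)
  res <- mr_presso(set, n_sim = 400, seed = 3)
  expect_identical(res$outliers$variant_id, "rs0000013")
  expect_lt(res$global_p, 0.05)
  expect_false(is.na(res$distortion_p))

  # distortion direction: an upward-displaced outlier inflates the all-SNP
  # estimate, so its removal moves the IVW estimate back down
  keep <- set$instruments$variant_id != "rs0000013"
  clean <- instrument_set(set$instruments[keep, , drop = FALSE])
  expect_lt(mr_ivw(clean)$beta, mr_ivw(set)$beta)
  expect_gt(res$distortion_coef, 0)

  # leave-one-out shifts most when the outlier is dropped
  loo <- leave_one_out(set)
  beta_all <- mr_ivw(set)$beta
  shift <- abs(loo$beta - beta_all)
  expect_identical(loo$dropped[which.max(shift)], "rs0000013")

  expect_error(mr_presso(set, n_sim = 50, seed = 1), "n_sim")
  expect_error(mr_presso(ratio_set(1:3 / 10, rep(0.1, 3)), n_sim = 100,
                         seed = 1), "at least 4")
})

test_that("doubling the PRESSO simulation count barely moves the global p", {
  sim <- simulate_two_sample(calib_config(seed = 71, n_snp = 30,
                                          beta_causal = 0.1))
  set <- set_from_sim(sim)
  p1 <- mr_presso(set, n_sim = 500, seed = 4)$global_p
  p2 <- mr_presso(set, n_sim = 1000, seed = 4)$global_p
  expect_lt(abs(p1 - p2), 2 / sqrt(500))
})

test_that("leave-one-out equals IVW on each (n-1)-subset", {
  sim <- simulate_two_sample(calib_config(seed = 88, n_snp = 12,
                                          beta_causal = 0.15))
  set <- set_from_sim(sim)
  loo <- leave_one_out(set)
  expect_equal(nrow(loo), 12L)
  for (j in c(2, 8, 12)) {
    sub <- instrument_set(set$instruments[-j, , drop = FALSE])
    expect_equal(loo$beta[j], mr_ivw(sub)$beta)
    expect_equal(loo$se[j], mr_ivw(sub)$se)
  }

  same <- ratio_set(rep(0.4, 5), rep(0.1, 5))
  loo_same <- leave_one_out(same)
  expect_equal(loo_same$beta, rep(0.4, 5))
  expect_equal(length(unique(loo_same$se)), 1L)
})

test_that("plot tables carry the definitional quantities", {
  sim <- simulate_two_sample(calib_config(seed = 5, n_snp = 10,
                                          beta_causal = 0.1))
  set <- set_from_sim(sim)
  ests <- list(mr_ivw(set), mr_egger(set))
  pd <- plot_data(set, ests)
  expect_equal(pd$scatter$lines$slope, c(ests[[1]]$beta, ests[[2]]$beta))
  expect_equal(pd$scatter$lines$intercept[2], ests[[2]]$extra$intercept)
  r <- wald_ratios(set)
  expect_equal(pd$funnel$beta, r$beta)
  expect_equal(pd$funnel$precision, 1 / r$se)
  summary_rows <- pd$forest[pd$forest$kind == "summary", ]
  expect_equal(summary_rows$beta[summary_rows$label == "IVW"],
               ests[[1]]$beta)
})

test_that("mr_diagnostics bundles all components consistently", {
  sim <- simulate_two_sample(calib_config(seed = 6, n_snp = 15,
                                          beta_causal = 0.1))
  set <- set_from_sim(sim)
  d <- mr_diagnostics(set, n_sim = 200, seed = 10)
  expect_equal(d$q_df, 14L)
  expect_equal(nrow(d$loo), 15L)
  expect_equal(d$q, cochran_q(set)$q)
  expect_equal(d$egger_intercept, egger_intercept_test(set)$intercept)
})
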