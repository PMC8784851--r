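# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Instrument set from raw vectors (already harmonized by construction).
toy_set <- function(beta_exp, se_exp, beta_out, se_out,
                    eaf = rep(0.5, length(beta_exp)),
                    n_exp = rep(1e4, length(beta_exp)),
                    ids = sprintf("rs%04d", seq_along(beta_exp))) {
  instrument_set(data.frame(
    variant_id = ids, beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out, eaf = eaf, eaf_out = eaf,
    n_exp = n_exp, pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    flipped = FALSE, proxy_used = FALSE, palindromic = FALSE,
    stringsAsFactors = FALSE))
}

# Instrument set with Wald ratios exactly `ratios` and ratio SEs `ses`
# (unit exposure effects).
ratio_set <- function(ratios, ses) {
  toy_set(beta_exp = rep(1, length(ratios)),
          se_exp = rep(1e-6, length(ratios)),
          beta_out = ratios, se_out = ses)
}

# Random summary-statistics records for round-trip and harmonization
# property tests.
random_records <- function(n, seed) {
  set.seed(seed)
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                 c("A", "T"), c("C", "G"))
  pick <- sample(nrow(pairs), n, replace = TRUE)
  data.frame(
    variant_id = sprintf("rs%06d", sample.int(1e6, n)),
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    eaf = round(runif(n, 0.01, 0.99), 6),
    beta = rnorm(n, 0, 0.1), se = runif(n, 1e-4, 0.05),
    pval = runif(n, .Machine$double.xmin, 1),
    n_total = sample.int(1e6, n),
    n_cases = sample.int(1e5, n), n_controls = sample.int(1e5, n),
    stringsAsFactors = FALSE)
}

# Fast path from a simulation (swap/flip/palindrome-free config assumed):
# builds the harmonized set directly from the two tables.
set_from_sim <- function(sim) {
  e <- sim$exposure$records
  o <- sim$outcome$records
  instrument_set(data.frame(
    variant_id = e$variant_id, beta_exp = e$beta, se_exp = e$se,
    beta_out = o$beta, se_out = o$se, eaf = e$eaf, eaf_out = o$eaf,
    n_exp = e$n_total, pval_exp = e$pval, flipped = FALSE,
    proxy_used = FALSE, palindromic = FALSE, stringsAsFactors = FALSE))
}

# Simulation config used by the calibration suites: aligned alleles only,
# so set_from_sim() applies, with the default cohort sizes.
calib_config <- function(seed, ...) {
  sim_config(n_palindromic = 0L, swap_fraction = 0, flip_fraction = 0,
             seed = seed, ...)
}
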