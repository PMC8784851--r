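make_exposure <- function(ids, pvals) {
  rec <- random_records(length(ids), seed = 99)
  rec$variant_id <- ids
  rec$pval <- pvals
  summary_stats(rec, trait_label = "exp")
}

test_that("clumping keeps the stronger of two linked SNPs", {
  exposure <- make_exposure(c("a", "b"), c(1e-9, 1e-10))
  ld <- ld_info(data.frame(id1 = "a", id2 = "b", r2 = 0.5))
  kept <- select_instruments(exposure, ld)
  expect_identical(as.character(kept), "b")  # b has the smaller p
  clumped <- attr(kept, "clumped")
  expect_identical(clumped$variant_id, "a")
  expect_identical(clumped$clumped_by, "b")

  # unlinked pair: both retained
  kept2 <- select_instruments(exposure, ld_info())
  expect_setequal(as.character(kept2), c("a", "b"))
})

test_that("no candidate below threshold aborts with a message", {
  exposure <- make_exposure(c("a", "b"), c(1e-4, 1e-5))
  expect_error(select_instruments(exposure, ld_info()),
               "no variants below")
})

test_that("clumping matches an independent matrix-based oracle (n <= 12)", {
  # Oracle: dense r2 matrix, explicit ordering, set-based acceptance test.
  oracle <- function(ids, pvals, r2mat, thr) {
    ord <- order(pvals, ids)
    kept <- integer(0)
    for (i in ord) {
      if (all(r2mat[i, kept] < thr)) kept <- c(kept, i)
    }
    ids[kept]
  }
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    ids <- sprintf("rs%03d", sample.int(999, n))
    pvals <- runif(n, 1e-20, 1e-9)
    r2mat <- matrix(0, n, n)
    pairs <- which(upper.tri(r2mat), arr.ind = TRUE)
    linked <- runif(nrow(pairs)) < 0.4
    r2mat[pairs[linked, , drop = FALSE]] <- runif(sum(linked))
    r2mat <- r2mat + t(r2mat)
    diag(r2mat) <- 1
    ld <- ld_info(data.frame(id1 = ids[pairs[linked, 1]],
                             id2 = ids[pairs[linked, 2]],
                             r2 = r2mat[pairs[linked, , drop = FALSE]]))
    exposure <- make_exposure(ids, pvals)
    got <- as.character(select_instruments(exposure, ld, r2_clump = 0.1))
    want <- oracle(ids, pvals, r2mat, 0.1)
    expect_identical(got, want)
    # result is a maximal independent set under the threshold
    sub <- r2mat[match(got, ids), match(got, ids), drop = FALSE]
    diag(sub) <- 0
    expect_true(all(sub < 0.1))
    # every discarded candidate is linked to some retained one
    for (v in setdiff(ids, got)) {
      expect_true(any(r2mat[match(v, ids), match(got, ids)] >= 0.1))
    }
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(8)
  n <- 10
  ids <- sprintf("rs%03d", 1:n)
  pvals <- runif(n, 1e-15, 1e-9)
  ld <- ld_info(data.frame(id1 = ids[1:4], id2 = ids[5:8],
                           r2 = c(0.9, 0.5, 0.0005, 0.2)))
  e1 <- make_exposure(ids, pvals)
  perm <- sample(n)
  e2 <- make_exposure(ids[perm], pvals[perm])
  expect_identical(as.character(select_instruments(e1, ld)),
                   as.character(select_instruments(e2, ld)))
})

test_that("proxy search takes the max-r2 candidate above the threshold", {
  out_rec <- random_records(3, seed = 11)
  out_rec$variant_id <- c("p1", "p2", "p3")
  outcome <- summary_stats(out_rec)
  exp_rec <- random_records(4, seed = 12)
  exp_rec$variant_id <- c("target", "p1", "p2", "p3")
  exp_rec$pval <- c(1e-10, 1e-9, 1e-8, 1e-7)
  exposure <- summary_stats(exp_rec)
  ld <- ld_info(data.frame(id1 = "target", id2 = c("p1", "p2", "p3"),
                           r2 = c(0.7, 0.9, 0.3)))
  proxy <- find_proxy("target", exposure, outcome, ld)
  expect_identical(as.character(proxy), "p2")
  expect_equal(attr(proxy, "r2"), 0.9)

  # nothing above the threshold -> none (threshold is strict)
  ld2 <- ld_info(data.frame(id1 = "target", id2 = c("p1", "p2"),
                            r2 = c(0.5, 0.6)))
  expect_identical(find_proxy("target", exposure, outcome, ld2),
                   NA_character_)

  # tie on r2 -> lower exposure p wins
  ld3 <- ld_info(data.frame(id1 = "target", id2 = c("p1", "p2"),
                            r2 = c(0.8, 0.8)))
  expect_identical(as.character(find_proxy("target", exposure, outcome,
                                           ld3)), "p1")
})

harm_tables <- function(exp_alleles, out_alleles, beta_out = 0.05,
                        eaf = 0.3, eaf_out = 0.3) {
  exp_rec <- data.frame(variant_id = "rs1",
                        effect_allele = exp_alleles[1],
                        other_allele = exp_alleles[2],
                        eaf = eaf, beta = 0.1, se = 0.01, pval = 1e-10,
                        n_total = 1e5, n_cases = NA, n_controls = NA)
  out_rec <- exp_rec
  out_rec$effect_allele <- out_alleles[1]
  out_rec$other_allele <- out_alleles[2]
  out_rec$beta <- beta_out
  out_rec$eaf <- eaf_out
  list(exposure = summary_stats(exp_rec), outcome = summary_stats(out_rec))
}

test_that("harmonize handles aligned, swapped, complemented and bad alleles", {
  t1 <- harm_tables(c("A", "G"), c("A", "G"))
  s1 <- harmonize(t1$exposure, t1$outcome, "rs1")
  expect_equal(s1$instruments$beta_out, 0.05)
  expect_false(s1$instruments$flipped)

  t2 <- harm_tables(c("A", "G"), c("G", "A"), eaf_out = 0.7)
  s2 <- harmonize(t2$exposure, t2$outcome, "rs1")
  expect_equal(s2$instruments$beta_out, -0.05)
  expect_true(s2$instruments$flipped)
  expect_equal(s2$instruments$eaf_out, 0.3)

  # outcome on the other strand: T/C complements to A/G
  t3 <- harm_tables(c("A", "G"), c("T", "C"))
  s3 <- harmonize(t3$exposure, t3$outcome, "rs1")
  expect_equal(s3$instruments$beta_out, 0.05)
  expect_false(s3$instruments$flipped)
  expect_match(s3$provenance$detail, "strand_complemented")

  # strand complement plus swap
  t4 <- harm_tables(c("A", "G"), c("C", "T"))
  s4 <- harmonize(t4$exposure, t4$outcome, "rs1")
  expect_equal(s4$instruments$beta_out, -0.05)
  expect_true(s4$instruments$flipped)

  # irreconcilable allele sets are dropped with a reason
  t5 <- harm_tables(c("A", "G"), c("A", "C"))
  s5 <- harmonize(t5$exposure, t5$outcome, "rs1")
  expect_equal(n_instruments(s5), 0L)
  expect_identical(s5$provenance$detail, "alleles_irreconcilable")
})

test_that("palindromic SNPs with intermediate frequency are dropped", {
  tpal <- harm_tables(c("A", "T"), c("A", "T"), eaf = 0.5)
  spal <- harmonize(tpal$exposure, tpal$outcome, "rs1")
  expect_equal(n_instruments(spal), 0L)
  expect_identical(spal$provenance$detail, "palindrome_intermediate_eaf")

  # window edges: eaf exactly 0.4 is kept (window is open)
  tedge <- harm_tables(c("C", "G"), c("C", "G"), eaf = 0.4)
  expect_equal(n_instruments(harmonize(tedge$exposure, tedge$outcome,
                                       "rs1")), 1L)
  tkeep <- harm_tables(c("A", "T"), c("A", "T"), eaf = 0.1)
  skeep <- harmonize(tkeep$exposure, tkeep$outcome, "rs1")
  expect_equal(n_instruments(skeep), 1L)
  expect_true(skeep$instruments$palindromic)

  # palindromic without an exposure EAF cannot be checked -> dropped
  tna <- harm_tables(c("A", "T"), c("A", "T"))
  tna$exposure$records$eaf <- NA_real_
  sna <- suppressWarnings(harmonize(tna$exposure, tna$outcome, "rs1"))
  expect_identical(sna$provenance$detail, "palindromic_no_eaf")
})

test_that("harmonize is idempotent and strand-complement invariant", {
  sim <- simulate_two_sample(sim_config(n_snp = 60, seed = 314,
                                        beta_causal = 0.1,
                                        n_palindromic = 6))
  ids <- sim$exposure$records$variant_id
  set1 <- harmonize(sim$exposure, sim$outcome, ids)

  # idempotence: re-express the harmonized outcome on the exposure alleles
  # and harmonize again; nothing may change
  out2 <- sim$exposure$records
  out2$beta <- NA_real_
  keep <- match(set1$instruments$variant_id, out2$variant_id)
  out2 <- out2[keep, ]
  out2$beta <- set1$instruments$beta_out
  out2$se <- set1$instruments$se_out
  out2$eaf <- set1$instruments$eaf_out
  set2 <- harmonize(sim$exposure, summary_stats(out2),
                    set1$instruments$variant_id)
  expect_equal(set2$instruments$beta_out, set1$instruments$beta_out)
  expect_equal(set2$instruments$beta_exp, set1$instruments$beta_exp)
  expect_false(any(set2$instruments$flipped))

  # complementing a non-palindromic outcome record's strand changes nothing
  out3 <- sim$outcome$records
  nonpal <- !mapply(is_palindromic_pair, out3$effect_allele,
                    out3$other_allele)
  out3$effect_allele[nonpal] <- complement_allele(out3$effect_allele[nonpal])
  out3$other_allele[nonpal] <- complement_allele(out3$other_allele[nonpal])
  set3 <- harmonize(sim$exposure, summary_stats(out3), ids)
  expect_equal(set3$instruments$beta_out, set1$instruments$beta_out)
  expect_equal(set3$instruments$beta_exp, set1$instruments$beta_exp)
})

test_that("variance explained matches hand arithmetic and is monotone", {
  # beta .1, eaf .5, se .01, n 1e4: 0.005 / (0.005 + 0.5)
  expect_equal(variance_explained(0.1, 0.01, 0.5, 1e4), 0.005 / 0.505)
  expect_equal(variance_explained(0, 0.01, 0.3, 1e4), 0)
  expect_gt(variance_explained(0.2, 0.01, 0.5, 1e4),
            variance_explained(0.1, 0.01, 0.5, 1e4))
  expect_true(is.na(variance_explained(0.1, 0.01, NA, 1e4)))
})

test_that("F-statistic evaluates the printed formula exactly", {
  expect_equal(as.numeric(f_statistic(0.5, 4)), 2)
  expect_equal(as.numeric(f_statistic(0.01, 1002)), 0.01 * 1000 / 0.99)
  f0 <- f_statistic(0, 100)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "weak"))
  expect_error(f_statistic(1, 100), "r2")
  expect_error(f_statistic(0.5, 2), "n")
})
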