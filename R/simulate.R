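# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# The generator emulates the shape of a post-selection instrument panel for
# a binary exposure tested against a binary outcome: per-SNP true
# SNP-exposure effects gamma_j large enough to be genome-wide significant,
# a pleiotropic path alpha_j under a configurable law, true SNP-outcome
# effects Gamma_j = beta_causal * gamma_j + alpha_j, and observed effects
# drawn around the truths with binary-trait standard errors
# SE = 1 / sqrt(2 N f (1-f) K (1-K)). Palindromic variants, strand flips,
# allele swaps, planted outliers and block LD exercise every harmonization
# and diagnostic code path.

#' Configuration of a synthetic two-sample GWAS
#'
#' @param n_snp Number of instruments (default 150, the order of magnitude
#'   of a large binary-trait instrument panel).
#' @param n_exp,n_out Exposure/outcome sample sizes.
#' @param k_exp,k_out Case fractions, in (0, 1).
#' @param beta_causal True causal log-odds effect of exposure on outcome.
#' @param gamma_law Law of the true SNP-exposure effects: list with `sd`
#'   (normal scale) and `min_z` (truncation: draws are rejected until
#'   `|gamma| > min_z * se_exp`, emulating genome-wide-significant
#'   post-selection instruments; default `min_z = qnorm(1 - 5e-8/2)`).
#' @param pleiotropy List with `type` in `c("none", "balanced",
#'   "directional")` and, as applicable, `sd` and `mean` of the pleiotropic
#'   effects alpha_j.
#' @param inside_violated When TRUE, alpha_j gains a component proportional
#'   to gamma_j (`+ 0.3 * gamma_j`), violating the InSIDE assumption.
#' @param eaf_law List `(min, max)`: allele frequencies drawn uniformly on
#'   the interval (default (0.05, 0.95)).
#' @param n_palindromic Number of A/T or C/G variants injected (default 2).
#' @param outliers data.frame `(index, displacement)` or list of
#'   length-2 vectors: SNP `index`'s observed outcome beta is displaced by
#'   `displacement` outcome SEs.
#' @param ld_blocks Optional list `(n_blocks, block_size, r2)`: the first
#'   `n_blocks * block_size` SNPs form LD blocks with the stated pairwise
#'   within-block r-squared.
#' @param swap_fraction Fraction of non-palindromic SNPs whose outcome
#'   record reports the opposite effect allele (harmonization swap path).
#' @param flip_fraction Fraction whose outcome record is written on the
#'   opposite strand (complemented alleles; harmonization strand path).
#' @param seed Root seed (required; all randomness derives from it).
#' @return Validated list of class `SimConfig`.
#' @export
sim_config <- function(n_snp = 150L,
                       n_exp = 394283, k_exp = 46802 / 394283,
                       n_out = 1683768, k_out = 38984 / 1683768,
                       beta_causal = 0,
                       gamma_law = list(sd = 0.065,
                                        min_z = stats::qnorm(1 - 5e-8 / 2)),
                       pleiotropy = list(type = "none"),
                       inside_violated = FALSE,
                       eaf_law = list(min = 0.05, max = 0.95),
                       n_palindromic = 2L,
                       outliers = NULL,
                       ld_blocks = NULL,
                       swap_fraction = 0.15,
                       flip_fraction = 0.1,
                       seed) {
  stopifnot(n_snp >= 1, n_exp > 2, n_out > 2,
            k_exp > 0, k_exp < 1, k_out > 0, k_out < 1,
            gamma_law$sd > 0,
            eaf_law$min > 0, eaf_law$max < 1, eaf_law$min < eaf_law$max,
            n_palindromic >= 0, n_palindromic <= n_snp,
            swap_fraction >= 0, swap_fraction <= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            is_scalar_number(seed))
  pleiotropy$type <- match.arg(pleiotropy$type,
                               c("none", "balanced", "directional"))
  if (pleiotropy$type != "none" && (pleiotropy$sd %||% 0) <= 0) {
    stop("pleiotropy regime '", pleiotropy$type, "' needs sd > 0")
  }
  if (!is.null(outliers)) {
    if (!is.data.frame(outliers)) {
      outliers <- do.call(rbind, lapply(outliers, function(o) {
        data.frame(index = o[[1]], displacement = o[[2]])
      }))
    }
    stopifnot(all(outliers$index >= 1), all(outliers$index <= n_snp))
  }
  if (!is.null(ld_blocks)) {
    stopifnot(ld_blocks$n_blocks >= 1, ld_blocks$block_size >= 2,
              ld_blocks$r2 >= 0, ld_blocks$r2 <= 1,
              ld_blocks$n_blocks * ld_blocks$block_size <= n_snp)
  }
  structure(list(n_snp = as.integer(n_snp), n_exp = n_exp, k_exp = k_exp,
                 n_out = n_out, k_out = k_out, beta_causal = beta_causal,
                 gamma_law = gamma_law, pleiotropy = pleiotropy,
                 inside_violated = inside_violated, eaf_law = eaf_law,
                 n_palindromic = as.integer(n_palindromic),
                 outliers = outliers, ld_blocks = ld_blocks,
                 swap_fraction = swap_fraction,
                 flip_fraction = flip_fraction, seed = seed),
            class = "SimConfig")
}

# Binary-trait summary-statistic SE approximation.
binary_se <- function(n, f, k) 1 / sqrt(2 * n * f * (1 - f) * k * (1 - k))

NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

clamp_p <- function(p) pmax(p, .Machine$double.xmin)

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' See [sim_config()] for the generating model. Fully reproducible from the
#' config seed; every random stage uses its own derived stream so a change
#' in one stage does not perturb the others.
#'
#' @param config A [sim_config()] object.
#' @return List with `exposure` and `outcome` ([summary_stats()] objects),
#'   `truth` (object of class `SimTruth`: data.frame of per-SNP `gamma`,
#'   `alpha`, `Gamma`, `eaf`, `se_exp`, `se_out` plus attributes `config`
#'   and `r2_true`), and `ld` (an [ld_info()] with the block structure, or
#'   an empty table when `ld_blocks` is NULL).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_snp
  ids <- sprintf("rs%07d", seq_len(n))

  set.seed(derive_seed(config$seed, 1))
  eaf <- stats::runif(n, config$eaf_law$min, config$eaf_law$max)
  se_exp <- binary_se(config$n_exp, eaf, config$k_exp)
  se_out <- binary_se(config$n_out, eaf, config$k_out)

  # Alleles: palindromic indices drawn first, then pair assignment.
  pal_idx <- if (config$n_palindromic > 0L) {
    sort(sample.int(n, config$n_palindromic))
  } else integer(0)
  a1 <- a2 <- character(n)
  pick_np <- sample.int(nrow(NONPAL_PAIRS), n, replace = TRUE)
  a1 <- NONPAL_PAIRS[pick_np, 1]
  a2 <- NONPAL_PAIRS[pick_np, 2]
  if (length(pal_idx) > 0L) {
    pick_p <- sample.int(nrow(PAL_PAIRS), length(pal_idx), replace = TRUE)
    a1[pal_idx] <- PAL_PAIRS[pick_p, 1]
    a2[pal_idx] <- PAL_PAIRS[pick_p, 2]
  }

  # True SNP-exposure effects: truncated normal (rejection sampling against
  # each SNP's theoretical SE) so instruments are genome-wide significant.
  set.seed(derive_seed(config$seed, 2))
  min_z <- config$gamma_law$min_z %||% 0
  gamma <- stats::rnorm(n, 0, config$gamma_law$sd)
  for (iter in seq_len(10000L)) {
    weak <- which(abs(gamma) < min_z * se_exp)
    if (length(weak) == 0L) break
    gamma[weak] <- stats::rnorm(length(weak), 0, config$gamma_law$sd)
  }
  if (any(abs(gamma) < min_z * se_exp)) {
    stop("gamma_law too weak to yield genome-wide-significant instruments ",
         "at these sample sizes; increase sd or lower min_z")
  }
  # Effect alleles are oriented to the exposure-increasing allele (the
  # convention for reported instruments), so gamma_j >= 0 and directional
  # pleiotropy keeps a fixed sign relative to instrument orientation.
  gamma <- abs(gamma)

  set.seed(derive_seed(config$seed, 3))
  alpha <- switch(config$pleiotropy$type,
    none = numeric(n),
    balanced = stats::rnorm(n, 0, config$pleiotropy$sd),
    directional = stats::rnorm(n, config$pleiotropy$mean,
                               config$pleiotropy$sd))
  if (config$inside_violated) alpha <- alpha + 0.3 * gamma
  Gamma <- config$beta_causal * gamma + alpha

  set.seed(derive_seed(config$seed, 4))
  beta_exp_hat <- stats::rnorm(n, gamma, se_exp)
  beta_out_hat <- stats::rnorm(n, Gamma, se_out)
  if (!is.null(config$outliers)) {
    idx <- config$outliers$index
    beta_out_hat[idx] <- beta_out_hat[idx] +
      config$outliers$displacement * se_out[idx]
  }

  exposure <- summary_stats(
    data.frame(variant_id = ids, effect_allele = a1, other_allele = a2,
               eaf = eaf, beta = beta_exp_hat, se = se_exp,
               pval = clamp_p(2 * stats::pnorm(-abs(beta_exp_hat / se_exp))),
               n_total = config$n_exp,
               n_cases = round(config$n_exp * config$k_exp),
               n_controls = round(config$n_exp * (1 - config$k_exp)),
               stringsAsFactors = FALSE),
    trait_label = "simulated_exposure",
    ancestry = "simulated",
    n_cases = round(config$n_exp * config$k_exp),
    n_controls = round(config$n_exp * (1 - config$k_exp)))

  # Outcome representation: a fraction of non-palindromic SNPs are written
  # with swapped alleles (negated beta, reflected EAF) and a further
  # fraction on the complementary strand; harmonize() must undo both.
  set.seed(derive_seed(config$seed, 5))
  o1 <- a1
  o2 <- a2
  beta_out_rep <- beta_out_hat
  eaf_out <- eaf
  nonpal <- setdiff(seq_len(n), pal_idx)
  n_swap <- round(config$swap_fraction * length(nonpal))
  n_flip <- round(config$flip_fraction * length(nonpal))
  perm <- sample(nonpal)
  swap_idx <- perm[seq_len(n_swap)]
  flip_idx <- perm[n_swap + seq_len(n_flip)]
  if (length(swap_idx) > 0L) {
    tmp <- o1[swap_idx]
    o1[swap_idx] <- o2[swap_idx]
    o2[swap_idx] <- tmp
    beta_out_rep[swap_idx] <- -beta_out_rep[swap_idx]
    eaf_out[swap_idx] <- 1 - eaf_out[swap_idx]
  }
  if (length(flip_idx) > 0L) {
    o1[flip_idx] <- complement_allele(o1[flip_idx])
    o2[flip_idx] <- complement_allele(o2[flip_idx])
  }

  outcome <- summary_stats(
    data.frame(variant_id = ids, effect_allele = o1, other_allele = o2,
               eaf = eaf_out, beta = beta_out_rep, se = se_out,
               pval = clamp_p(2 * stats::pnorm(-abs(beta_out_rep / se_out))),
               n_total = config$n_out,
               n_cases = round(config$n_out * config$k_out),
               n_controls = round(config$n_out * (1 - config$k_out)),
               stringsAsFactors = FALSE),
    trait_label = "simulated_outcome",
    ancestry = "simulated",
    n_cases = round(config$n_out * config$k_out),
    n_controls = round(config$n_out * (1 - config$k_out)))

  ld_pairs <- data.frame(id1 = character(), id2 = character(),
                         r2 = numeric(), stringsAsFactors = FALSE)
  if (!is.null(config$ld_blocks)) {
    b <- config$ld_blocks
    for (blk in seq_len(b$n_blocks)) {
      members <- ids[(blk - 1L) * b$block_size + seq_len(b$block_size)]
      cmb <- utils::combn(members, 2)
      ld_pairs <- rbind(ld_pairs,
                        data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                                   r2 = b$r2, stringsAsFactors = FALSE))
    }
  }

  truth <- data.frame(variant_id = ids, gamma = gamma, alpha = alpha,
                      Gamma = Gamma, eaf = eaf, se_exp = se_exp,
                      se_out = se_out, stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  attr(truth, "r2_true") <- sum(gamma^2 / (gamma^2 + config$n_exp * se_exp^2))
  class(truth) <- c("SimTruth", class(truth))

  list(exposure = exposure, outcome = outcome, truth = truth,
       ld = ld_info(ld_pairs, panel_label = "simulated"))
}

# Cohort presets mirroring the six exposure-outcome study-size cells of a
# large asthma / respiratory-infection two-sample design: an "asthma"
# exposure panel (161 candidate instruments, 46,802 cases / 347,481
# controls) and a "msasthma" (moderate-to-severe) panel (24 instruments,
# 10,549 cases / 47,146 controls), each against outcome studies sized as
# susceptibility (38,984 / 1,644,784), hospitalization (9,986 / 1,877,672)
# and severe disease (5,101 / 1,383,241).
fixture_presets <- function() {
  exp_asthma <- list(n_snp = 161L, n_exp = 394283, k_exp = 46802 / 394283)
  exp_ms <- list(n_snp = 24L, n_exp = 57695, k_exp = 10549 / 57695)
  out_susc <- list(n_out = 38984 + 1644784, k_out = 38984 / (38984 + 1644784))
  out_hosp <- list(n_out = 9986 + 1877672, k_out = 9986 / (9986 + 1877672))
  out_sev <- list(n_out = 5101 + 1383241, k_out = 5101 / (5101 + 1383241))
  list(
    asthma_susceptibility = c(exp_asthma, out_susc),
    asthma_hospitalization = c(exp_asthma, out_hosp),
    asthma_severe = c(exp_asthma, out_sev),
    msasthma_susceptibility = c(exp_ms, out_susc),
    msasthma_hospitalization = c(exp_ms, out_hosp),
    msasthma_severe = c(exp_ms, out_sev)
  )
}

#' Write a named synthetic fixture to disk
#'
#' Generates one of the documented cohort presets and writes
#' `exposure.tsv`, `outcome.tsv`, `ld.tsv` and `truth.tsv` (per-SNP
#' `variant_id`, `gamma`, `alpha`, `Gamma`) in the canonical formats.
#' Presets: `asthma_susceptibility`, `asthma_hospitalization`,
#' `asthma_severe`, `msasthma_susceptibility`, `msasthma_hospitalization`,
#' `msasthma_severe`.
#'
#' @param name Preset name.
#' @param dir Output directory (created if absent).
#' @param seed Root seed (default 1).
#' @param ... Overrides passed on to [sim_config()] (e.g. `beta_causal`,
#'   `pleiotropy`, `outliers`).
#' @return Named character vector of the four file paths, invisibly.
#' @export
make_fixture <- function(name, dir, seed = 1, ...) {
  presets <- fixture_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(c(presets[[name]], list(seed = seed)), list(...))
  config <- do.call(sim_config, args)
  sim <- simulate_two_sample(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_summary_stats(sim$exposure, paths["exposure"])
  write_summary_stats(sim$outcome, paths["outcome"])
  write_ld(sim$ld, paths["ld"])
  write_tsv(sim$truth[c("variant_id", "gamma", "alpha", "Gamma")],
            paths["truth"])
  invisible(paths)
}
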