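# Config-driven orchestration: selection -> proxy substitution ->
# harmonization -> estimation -> diagnostics -> power, with provenance and
# deterministic, machine-readable reports.

#' Build or read an analysis configuration
#'
#' Either pass a path to a flat-key configuration file (Debian-control
#' `field: value` format, one analysis per file) or the fields themselves.
#' File fields mirror the argument names; `outcome` may list several
#' comma-separated paths (one report row per exposure-outcome pair).
#'
#' @param path Optional path to a config file; file fields are overridden
#'   by any argument supplied explicitly.
#' @param exposure Path to the exposure summary-statistics file.
#' @param outcome Character vector of outcome summary-statistics paths.
#' @param ld Optional path to a pairwise LD table.
#' @param exposure_dialect,outcome_dialect Dialect preset names
#'   (see [dialect_preset()]).
#' @param p_threshold Instrument significance threshold (default `5e-8`).
#' @param r2_clump Clumping r-squared threshold (default `0.001`).
#' @param r2_proxy Minimum proxy r-squared (default `0.6`).
#' @param palindrome_maf_limit Palindrome window edge (default `0.4`).
#' @param methods Estimators to run (default all four).
#' @param n_boot Bootstrap replicates for median/mode SEs (default 1000).
#' @param presso_n_sim MR-PRESSO simulation count (default 1000).
#' @param seed Root seed (required).
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @return List of class `AnalysisConfig`.
#' @export
analysis_config <- function(path = NULL, exposure = NULL, outcome = NULL,
                            ld = NULL, exposure_dialect = "generic",
                            outcome_dialect = "generic",
                            p_threshold = 5e-8, r2_clump = 0.001,
                            r2_proxy = 0.6, palindrome_maf_limit = 0.4,
                            methods = c("IVW", "weighted_median",
                                        "weighted_mode", "MR_Egger"),
                            n_boot = 1000L, presso_n_sim = 1000L,
                            seed = NULL, out_dir = NULL) {
  supplied <- names(match.call())[-1]
  cfg <- list(exposure = exposure, outcome = outcome, ld = ld,
              exposure_dialect = exposure_dialect,
              outcome_dialect = outcome_dialect,
              p_threshold = p_threshold, r2_clump = r2_clump,
              r2_proxy = r2_proxy,
              palindrome_maf_limit = palindrome_maf_limit,
              methods = methods, n_boot = n_boot,
              presso_n_sim = presso_n_sim, seed = seed, out_dir = out_dir)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- read.dcf(path)
    file_cfg <- stats::setNames(as.list(raw[1, ]), colnames(raw))
    for (key in names(file_cfg)) {
      if (!key %in% names(cfg)) stop("unknown config field: ", key)
      if (key %in% supplied) next  # explicit argument wins
      val <- file_cfg[[key]]
      cfg[[key]] <- switch(key,
        outcome = , methods = trimws(strsplit(val, ",")[[1]]),
        p_threshold = , r2_clump = , r2_proxy = ,
        palindrome_maf_limit = as.numeric(val),
        n_boot = , presso_n_sim = , seed = as.integer(val),
        val)
    }
  }
  if (is.null(cfg$exposure) || is.null(cfg$outcome)) {
    stop("config must name an exposure and at least one outcome file")
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$r2_clump > 0, cfg$r2_clump < 1,
            cfg$r2_proxy > 0, cfg$r2_proxy < 1,
            cfg$palindrome_maf_limit >= 0, cfg$palindrome_maf_limit <= 0.5)
  structure(cfg, class = "AnalysisConfig")
}

config_echo <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # keep logs location-agnostic
  vals <- vapply(cfg, function(v) paste(format(v), collapse = ","),
                 character(1))
  paste0(names(cfg), ": ", vals)
}

#' Run the full two-sample MR analysis described by a configuration
#'
#' Pipeline stages, per outcome: read and validate inputs; greedy LD
#' clumping of genome-wide-significant exposure variants; lookup in the
#' outcome table with proxy substitution for missing instruments (an
#' instrument with no proxy is removed); allele harmonization with
#' palindrome exclusion; the configured causal estimators; heterogeneity
#' and pleiotropy diagnostics (Cochran Q, Egger intercept, MR-PRESSO,
#' leave-one-out); when MR-PRESSO flags outliers, a secondary
#' outlier-removed IVW estimate is added; and a binary-outcome power
#' summary from the instruments' cumulative variance explained and the
#' outcome's case/control counts. All randomness derives from the config
#' seed, so the full report is a pure function of (input files, config).
#'
#' @param config An [analysis_config()].
#' @return A `ReportBundle`: list with `estimates`, `diagnostics`,
#'   `outliers`, `loo`, `provenance`, `power` (data.frames), `plots`
#'   (per-outcome [plot_data()] lists), `sets` (per-outcome
#'   `InstrumentSet`s) and `log` (character). Written to
#'   `config$out_dir` when set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  exposure <- read_summary_stats(config$exposure,
                                 dialect = config$exposure_dialect)
  ld <- if (!is.null(config$ld)) read_ld(config$ld) else ld_info()
  selected <- select_instruments(exposure, ld,
                                 p_threshold = config$p_threshold,
                                 r2_clump = config$r2_clump)
  clumped <- attr(selected, "clumped")

  estimates <- list()
  diagnostics <- list()
  outlier_rows <- list()
  loo_rows <- list()
  prov_rows <- list()
  power_rows <- list()
  plots <- list()
  sets <- list()
  log_lines <- c(sprintf("tsmr %s on %s",
                         as.character(utils::packageVersion("tsmr")),
                         R.version.string),
                 "config:", config_echo(config))

  if (nrow(clumped) > 0L) {
    prov_rows[[length(prov_rows) + 1L]] <- data.frame(
      outcome = "(all)", variant_id = clumped$variant_id,
      decision = "clumped",
      detail = sprintf("by=%s;r2=%.4g", clumped$clumped_by, clumped$r2),
      stringsAsFactors = FALSE)
  }

  for (oi in seq_along(config$outcome)) {
    opath <- config$outcome[[oi]]
    outcome <- read_summary_stats(opath, dialect = config$outcome_dialect)
    olabel <- outcome$trait_label
    oseed <- derive_seed(config$seed, 1000 + oi)

    ids <- as.character(selected)
    present <- ids %in% outcome$records$variant_id
    proxied <- character(0)
    for (v in ids[!present]) {
      proxy <- find_proxy(v, exposure, outcome, ld, r2_min = config$r2_proxy)
      if (is.na(proxy)) {
        prov_rows[[length(prov_rows) + 1L]] <- data.frame(
          outcome = olabel, variant_id = v, decision = "removed",
          detail = "absent_from_outcome_no_proxy", stringsAsFactors = FALSE)
        ids <- setdiff(ids, v)
      } else {
        prov_rows[[length(prov_rows) + 1L]] <- data.frame(
          outcome = olabel, variant_id = v, decision = "proxied",
          detail = sprintf("proxy=%s;r2=%.4g", proxy, attr(proxy, "r2")),
          stringsAsFactors = FALSE)
        ids[ids == v] <- proxy
        proxied <- c(proxied, as.character(proxy))
      }
    }

    set <- harmonize(exposure, outcome, ids,
                     palindrome_maf_limit = config$palindrome_maf_limit)
    if (length(proxied) > 0L) {
      set$instruments$proxy_used <-
        set$instruments$variant_id %in% proxied
    }
    prov_rows[[length(prov_rows) + 1L]] <- cbind(
      data.frame(outcome = olabel, stringsAsFactors = FALSE),
      set$provenance)
    if (n_instruments(set) == 0L) {
      bundle_prov <- do.call(rbind, prov_rows)
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_tsv(bundle_prov, file.path(config$out_dir, "provenance.tsv"))
      }
      stop("no instruments survived harmonization for outcome '", olabel,
           "'; see provenance table")
    }

    ests <- mr_all_methods(set, n_boot = config$n_boot, seed = oseed,
                           methods = config$methods)
    diag <- mr_diagnostics(set, n_sim = config$presso_n_sim, seed = oseed)

    if (nrow(diag$presso$outliers) > 0L &&
        nrow(diag$presso$outliers) < n_instruments(set) - 1L) {
      keep <- !set$instruments$variant_id %in% diag$presso$outliers$variant_id
      sub <- instrument_set(set$instruments[keep, , drop = FALSE])
      fit <- mr_ivw(sub)
      fit$method <- "IVW_outlier_removed"
      ests$IVW_outlier_removed <- fit
    }

    est_df <- do.call(rbind, lapply(ests, as.data.frame))
    estimates[[olabel]] <- cbind(
      data.frame(exposure = exposure$trait_label, outcome = olabel,
                 stringsAsFactors = FALSE), est_df)
    diagnostics[[olabel]] <- data.frame(
      exposure = exposure$trait_label, outcome = olabel,
      q = diag$q, q_df = diag$q_df, q_pval = diag$q_pval,
      presso_global_p = diag$presso$global_p,
      presso_global_label = diag$presso$global_p_label,
      presso_distortion_p = diag$presso$distortion_p,
      egger_intercept = diag$egger_intercept,
      egger_intercept_pval = diag$egger_intercept_pval,
      stringsAsFactors = FALSE)
    if (nrow(diag$presso$outliers) > 0L) {
      outlier_rows[[olabel]] <- cbind(
        data.frame(outcome = olabel, stringsAsFactors = FALSE),
        diag$presso$outliers)
    }
    loo_rows[[olabel]] <- cbind(
      data.frame(outcome = olabel, stringsAsFactors = FALSE), diag$loo)
    power_rows[[olabel]] <- cbind(
      data.frame(exposure = exposure$trait_label, outcome = olabel,
                 stringsAsFactors = FALSE),
      power_summary(outcome$n_cases, outcome$n_controls, set$r2_total))
    plots[[olabel]] <- plot_data(set, ests)
    sets[[olabel]] <- set
    log_lines <- c(log_lines,
                   sprintf("%s: %d instruments, R2 = %.6g, mean F = %.6g",
                           olabel, n_instruments(set), set$r2_total,
                           set$f_mean))
  }

  bundle <- structure(list(
    estimates = do.call(rbind, c(estimates, list(make.row.names = FALSE))),
    diagnostics = do.call(rbind, c(diagnostics,
                                   list(make.row.names = FALSE))),
    outliers = if (length(outlier_rows) > 0L) {
      do.call(rbind, c(outlier_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(outcome = character(), variant_id = character(),
                 pval = numeric(), stringsAsFactors = FALSE)
    },
    loo = do.call(rbind, c(loo_rows, list(make.row.names = FALSE))),
    provenance = do.call(rbind, c(prov_rows, list(make.row.names = FALSE))),
    power = do.call(rbind, c(power_rows, list(make.row.names = FALSE))),
    plots = plots, sets = sets, log = log_lines, config = config
  ), class = "ReportBundle")

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to a directory
#'
#' Emits `estimates.tsv`, `diagnostics.tsv`, `outliers.tsv`, `loo.tsv`,
#' `provenance.tsv`, `power.tsv`, per-outcome `scatter_*`, `funnel_*` and
#' `forest_*` tables, and `run.log`. Output is deterministic: two runs of
#' the same config on the same inputs produce byte-identical files.
#'
#' @param bundle A `ReportBundle` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ReportBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$estimates, file.path(dir, "estimates.tsv"))
  write_tsv(bundle$diagnostics, file.path(dir, "diagnostics.tsv"))
  write_tsv(bundle$outliers, file.path(dir, "outliers.tsv"))
  write_tsv(bundle$loo, file.path(dir, "loo.tsv"))
  write_tsv(bundle$provenance, file.path(dir, "provenance.tsv"))
  write_tsv(bundle$power, file.path(dir, "power.tsv"))
  for (olabel in names(bundle$plots)) {
    p <- bundle$plots[[olabel]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", olabel)
    write_tsv(p$scatter$points, file.path(dir, paste0("scatter_", safe,
                                                      ".tsv")))
    write_tsv(p$scatter$lines, file.path(dir, paste0("scatter_lines_",
                                                     safe, ".tsv")))
    write_tsv(p$funnel, file.path(dir, paste0("funnel_", safe, ".tsv")))
    write_tsv(p$forest, file.path(dir, paste0("forest_", safe, ".tsv")))
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", nrow(x$estimates), "estimate rows across",
      length(x$sets), "outcome(s)\n")
  print(x$estimates[c("exposure", "outcome", "method", "nsnp", "or",
                      "ci_low", "ci_high", "pval")])
  invisible(x)
}
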