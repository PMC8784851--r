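# Instrument selection, proxy substitution, allele harmonization, and
# instrument-strength (R-squared / F-statistic) computation.

#' Select LD-independent genome-wide-significant instruments
#'
#' Greedy p-value-ranked clumping. Candidates with `pval < p_threshold` are
#' ranked by ascending p-value (ties broken by lexicographic variant ID) and
#' accepted one by one; a candidate is retained iff its r-squared with every
#' already-retained variant is below `r2_clump`. Pairs absent from `ld` are
#' treated as unlinked (r2 = 0). The result is deterministic and invariant
#' to the input row order.
#'
#' @param exposure A [summary_stats()] object for the exposure GWAS.
#' @param ld An [ld_info()] object.
#' @param p_threshold Genome-wide significance threshold (default `5e-8`).
#' @param r2_clump Clumping threshold (default `0.001`): retained pairs must
#'   have r-squared strictly below it.
#' @return Character vector of retained variant IDs, in acceptance order,
#'   with attribute `"clumped"`: a data.frame recording, for each discarded
#'   candidate, the retained index variant that removed it.
#' @export
select_instruments <- function(exposure, ld,
                               p_threshold = 5e-8, r2_clump = 0.001) {
  stopifnot(inherits(exposure, "SummaryStats"), inherits(ld, "LDInfo"),
            p_threshold > 0, p_threshold < 1, r2_clump > 0, r2_clump < 1)
  rec <- exposure$records
  cand <- rec[rec$pval < p_threshold, c("variant_id", "pval")]
  if (nrow(cand) == 0L) {
    stop("no variants below the significance threshold p < ", p_threshold,
         " in exposure '", exposure$trait_label, "'")
  }
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  clumped <- data.frame(variant_id = character(), clumped_by = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    v <- cand$variant_id[i]
    if (length(kept) == 0L) {
      kept <- v
      next
    }
    r2 <- ld_r2(ld, v, kept)
    hit <- which(r2 >= r2_clump)
    if (length(hit) == 0L) {
      kept <- c(kept, v)
    } else {
      clumped <- rbind(clumped, data.frame(
        variant_id = v, clumped_by = kept[hit[1L]], r2 = r2[hit[1L]],
        stringsAsFactors = FALSE))
    }
  }
  structure(kept, clumped = clumped)
}

#' Find a proxy variant for an instrument missing from the outcome GWAS
#'
#' Among variants present in both the exposure and outcome tables, returns
#' the one with the largest r-squared to `target`, provided it exceeds
#' `r2_min`; ties are broken by the smaller exposure p-value, then by
#' lexicographic variant ID. Returns `NA` when no candidate qualifies (the
#' instrument is then dropped).
#'
#' @param target Variant ID absent from the outcome GWAS.
#' @param exposure,outcome [summary_stats()] objects.
#' @param ld An [ld_info()] object.
#' @param r2_min Minimum r-squared for an acceptable proxy (default `0.6`,
#'   strict inequality).
#' @return A length-1 character vector (the proxy ID, with attribute `"r2"`)
#'   or `NA_character_`.
#' @export
find_proxy <- function(target, exposure, outcome, ld, r2_min = 0.6) {
  stopifnot(inherits(exposure, "SummaryStats"),
            inherits(outcome, "SummaryStats"), inherits(ld, "LDInfo"))
  shared <- intersect(exposure$records$variant_id,
                      outcome$records$variant_id)
  shared <- setdiff(shared, target)
  if (length(shared) == 0L) return(NA_character_)
  r2 <- ld_r2(ld, target, shared)
  ok <- r2 > r2_min
  if (!any(ok)) return(NA_character_)
  shared <- shared[ok]
  r2 <- r2[ok]
  p_exp <- exposure$records$pval[match(shared, exposure$records$variant_id)]
  ord <- order(-r2, p_exp, shared)
  structure(shared[ord[1L]], r2 = r2[ord[1L]])
}

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' For each instrument: (i) if the outcome's effect/other alleles match the
#' exposure's, the record is kept as is; (ii) if they are swapped, the
#' outcome beta is negated and its EAF reflected, and the variant is flagged
#' `flipped`; (iii) if taking the strand complement of the outcome alleles
#' produces a match, the complement is applied first and then (i)/(ii);
#' (iv) palindromic variants (A/T or C/G) whose exposure effect-allele
#' frequency lies in the intermediate window
#' `(palindrome_maf_limit, 1 - palindrome_maf_limit)` are dropped (strand
#' unresolvable); (v) irreconcilable allele sets are dropped. Every
#' exclusion is recorded in the provenance table. Palindromic variants
#' lacking an exposure EAF cannot be checked and are dropped with reason
#' `"palindromic_no_eaf"`.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param instrument_ids Variant IDs to harmonize; each must be present in
#'   both tables (substitute proxies beforehand).
#' @param palindrome_maf_limit Lower edge of the intermediate-frequency
#'   window (default `0.4`, i.e. the window is `(0.4, 0.6)`).
#' @return An `InstrumentSet`: list with elements `instruments` (data.frame
#'   `variant_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`,
#'   `eaf_out`, `n_exp`, `pval_exp`, `flipped`, `proxy_used`,
#'   `palindromic`), `provenance`, `r2_per_snp`, `r2_total`, `f_per_snp`,
#'   `f_mean`.
#' @export
harmonize <- function(exposure, outcome, instrument_ids,
                      palindrome_maf_limit = 0.4) {
  stopifnot(inherits(exposure, "SummaryStats"),
            inherits(outcome, "SummaryStats"),
            palindrome_maf_limit >= 0, palindrome_maf_limit <= 0.5)
  instrument_ids <- as.character(instrument_ids)
  exp_rec <- exposure$records
  out_rec <- outcome$records
  missing_exp <- setdiff(instrument_ids, exp_rec$variant_id)
  missing_out <- setdiff(instrument_ids, out_rec$variant_id)
  if (length(missing_exp) > 0L || length(missing_out) > 0L) {
    stop("instrument(s) absent from ",
         if (length(missing_exp) > 0L) "exposure" else "outcome", " table: ",
         paste(c(missing_exp, missing_out), collapse = ", "))
  }
  lo <- palindrome_maf_limit
  hi <- 1 - palindrome_maf_limit

  rows <- vector("list", length(instrument_ids))
  prov <- vector("list", length(instrument_ids))
  for (i in seq_along(instrument_ids)) {
    v <- instrument_ids[i]
    e <- exp_rec[match(v, exp_rec$variant_id), ]
    o <- out_rec[match(v, out_rec$variant_id), ]
    pal <- is_palindromic_pair(e$effect_allele, e$other_allele)

    if (pal) {
      if (is.na(e$eaf)) {
        prov[[i]] <- data.frame(variant_id = v, decision = "dropped",
                                detail = "palindromic_no_eaf",
                                stringsAsFactors = FALSE)
        next
      }
      if (e$eaf > lo && e$eaf < hi) {
        prov[[i]] <- data.frame(variant_id = v, decision = "dropped",
                                detail = "palindrome_intermediate_eaf",
                                stringsAsFactors = FALSE)
        next
      }
    }

    oa1 <- o$effect_allele
    oa2 <- o$other_allele
    strand_flipped <- FALSE
    # For a palindromic pair the complemented alleles equal the swapped
    # originals, so path (iii) is only meaningful for non-palindromic SNPs.
    if (!pal &&
        !(setequal(c(oa1, oa2), c(e$effect_allele, e$other_allele)))) {
      ca1 <- complement_allele(oa1)
      ca2 <- complement_allele(oa2)
      if (setequal(c(ca1, ca2), c(e$effect_allele, e$other_allele))) {
        oa1 <- ca1
        oa2 <- ca2
        strand_flipped <- TRUE
      }
    }

    beta_out <- o$beta
    eaf_out <- o$eaf
    flipped <- FALSE
    if (oa1 == e$effect_allele && oa2 == e$other_allele) {
      # aligned
    } else if (oa1 == e$other_allele && oa2 == e$effect_allele) {
      beta_out <- -beta_out
      eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
      flipped <- TRUE
    } else {
      prov[[i]] <- data.frame(variant_id = v, decision = "dropped",
                              detail = "alleles_irreconcilable",
                              stringsAsFactors = FALSE)
      next
    }

    rows[[i]] <- data.frame(
      variant_id = v, beta_exp = e$beta, se_exp = e$se,
      beta_out = beta_out, se_out = o$se, eaf = e$eaf, eaf_out = eaf_out,
      n_exp = e$n_total, pval_exp = e$pval,
      flipped = flipped, proxy_used = FALSE, palindromic = pal,
      stringsAsFactors = FALSE)
    detail <- c(if (flipped) "flipped",
                if (strand_flipped) "strand_complemented",
                if (pal) "palindromic_kept")
    prov[[i]] <- data.frame(
      variant_id = v, decision = "retained",
      detail = if (length(detail) > 0L) paste(detail, collapse = ";") else "",
      stringsAsFactors = FALSE)
  }

  inst <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(inst)) {
    inst <- data.frame(variant_id = character(), beta_exp = numeric(),
                       se_exp = numeric(), beta_out = numeric(),
                       se_out = numeric(), eaf = numeric(),
                       eaf_out = numeric(), n_exp = numeric(),
                       pval_exp = numeric(), flipped = logical(),
                       proxy_used = logical(), palindromic = logical(),
                       stringsAsFactors = FALSE)
  }
  rownames(inst) <- NULL
  instrument_set(inst, provenance = do.call(rbind, prov))
}

#' Construct an instrument set from a harmonized table
#'
#' Computes per-SNP variance explained and F-statistics and bundles them
#' with the instruments and their selection provenance.
#'
#' @param instruments data.frame as produced by [harmonize()].
#' @param provenance data.frame `(variant_id, decision, detail)`.
#' @return An object of class `InstrumentSet`.
#' @export
instrument_set <- function(instruments, provenance = NULL) {
  stopifnot(is.data.frame(instruments))
  if (nrow(instruments) > 0L) {
    stopifnot(all(instruments$se_exp > 0), all(instruments$se_out > 0))
  }
  r2 <- variance_explained(instruments$beta_exp, instruments$se_exp,
                           instruments$eaf, instruments$n_exp)
  f <- ifelse(is.na(r2) | is.na(instruments$n_exp), NA_real_,
              f_statistic(r2, instruments$n_exp))
  if (any(is.na(r2))) {
    warning(sum(is.na(r2)), " instrument(s) lack eaf or n; excluded from ",
            "cumulative R2")
  }
  structure(list(
    instruments = instruments,
    provenance = provenance %||%
      data.frame(variant_id = instruments$variant_id,
                 decision = "retained", detail = "",
                 stringsAsFactors = FALSE),
    r2_per_snp = r2,
    r2_total = sum(r2, na.rm = TRUE),
    f_per_snp = f,
    f_mean = if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  ), class = "InstrumentSet")
}

#' @export
print.InstrumentSet <- function(x, ...) {
  cat(sprintf("InstrumentSet: %d instruments\n", nrow(x$instruments)))
  cat(sprintf("  cumulative R2 = %.4g; mean F = %.4g (range %.4g-%.4g)\n",
              x$r2_total, x$f_mean,
              suppressWarnings(min(x$f_per_snp, na.rm = TRUE)),
              suppressWarnings(max(x$f_per_snp, na.rm = TRUE))))
  invisible(x)
}

#' Number of instruments in a set
#' @param set An `InstrumentSet`.
#' @return Integer count.
#' @export
n_instruments <- function(set) {
  stopifnot(inherits(set, "InstrumentSet"))
  nrow(set$instruments)
}

#' Per-SNP variance in the exposure explained by an instrument
#'
#' Summary-statistic approximation
#' \deqn{R^2_j = \frac{2\beta_j^2 f_j (1-f_j)}
#'   {2\beta_j^2 f_j (1-f_j) + 2 se_j^2 N f_j (1-f_j)}}
#' which algebraically reduces to \eqn{\beta^2 / (\beta^2 + N\,se^2)}.
#' Cumulative variance explained is the sum over instruments. Vectorised;
#' returns `NA` where `eaf` or `n` is missing.
#'
#' @param beta,se Per-SNP effect and standard error on the exposure.
#' @param eaf Effect-allele frequency.
#' @param n Exposure sample size.
#' @return Numeric vector of per-SNP R-squared contributions.
#' @export
variance_explained <- function(beta, se, eaf, n) {
  if (length(beta) == 0L) return(numeric(0))
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + 2 * se^2 * n * eaf * (1 - eaf)
  out <- num / den
  out[is.na(eaf) | is.na(n)] <- NA_real_
  out[!is.na(beta) & beta == 0 & !is.na(eaf) & !is.na(n)] <- 0
  out
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (n - 2) / (1 - R2)`. Values of `F <= 10` carry the
#' conventional weak-instrument flag (attribute `"weak"`).
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size, `> 2`.
#' @return F value(s) with logical attribute `"weak"`.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) {
    stop("r2 must lie in [0, 1)")
  }
  if (any(n <= 2, na.rm = TRUE)) stop("n must exceed 2")
  f <- r2 * (n - 2) / (1 - r2)
  structure(f, weak = f <= 10)
}
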