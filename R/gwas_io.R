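# Reading, validating and writing GWAS summary-statistics tables and
# pairwise LD information.
#
# The canonical on-disk format is tab-delimited text with the header
#   variant_id effect_allele other_allele eaf beta se pval n_total
#   [n_cases n_controls]
# Other layouts are mapped onto this one through a "dialect": a named
# character vector from canonical column name to the column name found in
# the file.

CANONICAL_COLUMNS <- c("variant_id", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pval", "n_total", "n_cases",
                       "n_controls")
MANDATORY_COLUMNS <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pval")

#' Column dialect presets for summary-statistics files
#'
#' A dialect maps the package's canonical column names onto the header names
#' found in a particular file. Two presets ship with the package: `"generic"`
#' (the canonical names themselves, i.e. a typical `beta`/`se`/`pval`
#' layout) and `"covid_hgi_r5"` (the COVID-19 Host Genetics Initiative
#' release-5 meta-analysis header). A user-supplied named character vector
#' overrides or extends a preset.
#'
#' @param name Preset name, `"generic"` or `"covid_hgi_r5"`.
#' @return Named character vector: canonical name -> file column name.
#' @export
#' @examples
#' dialect_preset("covid_hgi_r5")[["beta"]]
dialect_preset <- function(name = c("generic", "covid_hgi_r5")) {
  name <- match.arg(name)
  switch(name,
    generic = stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS),
    covid_hgi_r5 = c(
      variant_id    = "rsid",
      effect_allele = "ALT",
      other_allele  = "REF",
      eaf           = "all_meta_AF",
      beta          = "all_inv_var_meta_beta",
      se            = "all_inv_var_meta_sebeta",
      pval          = "all_inv_var_meta_p",
      n_cases       = "all_inv_var_meta_cases",
      n_controls    = "all_inv_var_meta_controls"
    )
  )
}

#' Construct a summary-statistics object
#'
#' Container for one GWAS's per-variant association records plus study-level
#' metadata. `records` must carry the canonical columns; variant IDs must be
#' unique.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n_total` and optionally
#'   `n_cases`, `n_controls`.
#' @param trait_label Human-readable trait name.
#' @param ancestry Ancestry label (free text).
#' @param n_cases,n_controls Study-level case/control counts (optional).
#' @return An object of class `SummaryStats`.
#' @export
summary_stats <- function(records, trait_label = "trait",
                          ancestry = "unspecified",
                          n_cases = NA_real_, n_controls = NA_real_) {
  stopifnot(is.data.frame(records))
  for (col in setdiff(CANONICAL_COLUMNS, names(records))) {
    records[[col]] <- NA_real_
  }
  records <- records[CANONICAL_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n_total", "n_cases",
                "n_controls")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in summary statistics: ",
         paste(unique(records$variant_id[duplicated(records$variant_id)]),
               collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(trait_label = trait_label, records = records,
                 ancestry = ancestry, n_cases = n_cases,
                 n_controls = n_controls),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("SummaryStats: %s (%s ancestry)\n", x$trait_label, x$ancestry))
  cat(sprintf("  %d variants; study cases/controls: %s / %s\n",
              nrow(x$records),
              format(x$n_cases), format(x$n_controls)))
  invisible(x)
}

# Per-row validation. Returns a data.frame (row, variant_id, problem) with
# one row per violation; zero rows means the table is clean.
validate_records <- function(rec) {
  problems <- list()
  note <- function(idx, what) {
    if (any(idx)) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = which(idx), variant_id = rec$variant_id[idx],
        problem = what, stringsAsFactors = FALSE)
    }
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  note(is.na(rec$variant_id) | rec$variant_id == "", "missing variant_id")
  note(!ok_allele(rec$effect_allele), "effect_allele not in {A,C,G,T}")
  note(!ok_allele(rec$other_allele), "other_allele not in {A,C,G,T}")
  note(ok_allele(rec$effect_allele) & ok_allele(rec$other_allele) &
         rec$effect_allele == rec$other_allele,
       "effect_allele equals other_allele")
  note(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf outside [0,1]")
  note(is.na(rec$beta), "missing beta")
  note(is.na(rec$se) | rec$se <= 0, "se not > 0")
  note(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1, "pval outside (0,1]")
  if (length(problems) == 0L) {
    return(data.frame(row = integer(), variant_id = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  out[order(out$row), , drop = FALSE]
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (TSV by default, CSV detected from the
#' header), maps its columns onto the canonical layout through a dialect,
#' upper-cases alleles, and validates every row. P-values equal to zero are
#' clamped to the smallest positive double with a warning. Rows violating
#' the record invariants are rejected: with `strict = TRUE` (default) the
#' read aborts with a per-row report; with `strict = FALSE` offending rows
#' are dropped, a warning summarises them, and the full validation log is
#' attached as attribute `"validation_log"`.
#'
#' @param path File path.
#' @param dialect Preset name (see [dialect_preset()]) or a named character
#'   vector mapping canonical names to file column names.
#' @param trait_label,ancestry Metadata stored on the result.
#' @param n_cases,n_controls Study-level counts; when missing they are taken
#'   as the maximum of the per-row columns if those are present.
#' @param strict Abort on any invalid row (default) or drop and report.
#' @return A [summary_stats()] object.
#' @export
read_summary_stats <- function(path, dialect = "generic",
                               trait_label = NULL, ancestry = "unspecified",
                               n_cases = NA_real_, n_controls = NA_real_,
                               strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- if (is.character(dialect) && is.null(names(dialect))) {
    dialect_preset(dialect)
  } else {
    utils::modifyList(as.list(dialect_preset("generic")), as.list(dialect))
  }
  map <- unlist(map)
  raw <- utils::read.delim(path, sep = sniff_sep(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  missing_cols <- setdiff(unname(map[MANDATORY_COLUMNS]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("mandatory column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  rec <- lapply(CANONICAL_COLUMNS, function(canon) {
    src <- if (canon %in% names(map)) map[[canon]] else NA_character_
    if (!is.na(src) && src %in% names(raw)) {
      raw[[src]]
    } else {
      rep(NA, nrow(raw))
    }
  })
  names(rec) <- CANONICAL_COLUMNS
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  rec$variant_id <- as.character(rec$variant_id)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n_total", "n_cases",
                "n_controls")) {
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  }
  if (all(is.na(rec$n_total)) && !all(is.na(rec$n_cases))) {
    rec$n_total <- rec$n_cases + rec$n_controls
  }
  zero_p <- !is.na(rec$pval) & rec$pval == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " zero p-value(s) clamped to smallest positive double")
    rec$pval[zero_p] <- .Machine$double.xmin
  }
  log <- validate_records(rec)
  if (nrow(log) > 0L) {
    if (strict) {
      stop("invalid rows in ", path, ":\n",
           paste(sprintf("  row %d (%s): %s", log$row, log$variant_id,
                         log$problem), collapse = "\n"))
    }
    warning(length(unique(log$row)), " invalid row(s) dropped from ", path)
    rec <- rec[-unique(log$row), , drop = FALSE]
  }
  if (is.na(n_cases) && !all(is.na(rec$n_cases))) {
    n_cases <- max(rec$n_cases, na.rm = TRUE)
  }
  if (is.na(n_controls) && !all(is.na(rec$n_controls))) {
    n_controls <- max(rec$n_controls, na.rm = TRUE)
  }
  out <- summary_stats(rec,
                       trait_label = trait_label %||%
                         tools::file_path_sans_ext(basename(path)),
                       ancestry = ancestry,
                       n_cases = n_cases, n_controls = n_controls)
  attr(out, "validation_log") <- log
  out
}

#' Write a summary-statistics table in the canonical format
#'
#' Tab-delimited, canonical header, 17-significant-digit numbers so that
#' [read_summary_stats()] inverts the write exactly (bit-identical doubles).
#'
#' @param stats A [summary_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "SummaryStats"))
  write_tsv(stats$records, path)
}

#' Construct pairwise LD information
#'
#' Stores pairwise r-squared values keyed by unordered variant pair. The
#' mapping is symmetric, r2(v, v) = 1 by convention, and any absent pair is
#' treated as r2 = 0 (unlinked).
#'
#' @param pairs data.frame with columns `id1`, `id2`, `r2`.
#' @param panel_label Label of the reference panel the values came from.
#' @return An object of class `LDInfo`.
#' @export
ld_info <- function(pairs = data.frame(id1 = character(),
                                       id2 = character(),
                                       r2 = numeric()),
                    panel_label = "unspecified") {
  stopifnot(is.data.frame(pairs),
            all(c("id1", "id2", "r2") %in% names(pairs)))
  pairs$id1 <- as.character(pairs$id1)
  pairs$id2 <- as.character(pairs$id2)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("r2 outside [0,1] in LD table")
  }
  self <- pairs$id1 == pairs$id2
  if (any(pairs$r2[self] != 1)) {
    stop("self pair with r2 != 1 in LD table")
  }
  pairs <- pairs[!self, , drop = FALSE]
  lo <- pmin(pairs$id1, pairs$id2)
  hi <- pmax(pairs$id1, pairs$id2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    # keep the first occurrence of each unordered pair
    pairs <- pairs[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(pairs)))
  if (nrow(pairs) > 0L) {
    for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(pairs = data.frame(id1 = pmin(pairs$id1, pairs$id2),
                                    id2 = pmax(pairs$id1, pairs$id2),
                                    r2 = pairs$r2,
                                    stringsAsFactors = FALSE),
                 panel_label = panel_label, index = env),
            class = "LDInfo")
}

#' Read a pairwise LD table
#'
#' Three-column delimited file `(id1, id2, r2)`; values outside `[0, 1]` are
#' rejected.
#'
#' @param path File path.
#' @param panel_label Stored on the result.
#' @return An [ld_info()] object.
#' @export
read_ld <- function(path, panel_label = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sniff_sep(path), header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("LD file must have three columns (id1, id2, r2)")
  names(raw)[1:3] <- c("id1", "id2", "r2")
  ld_info(raw[1:3], panel_label = panel_label)
}

#' Write pairwise LD information
#' @param ld An [ld_info()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "LDInfo"))
  write_tsv(ld$pairs, path)
}

#' Query pairwise r-squared
#'
#' Vectorised over `a`/`b`. Returns 1 for identical IDs and 0 for any pair
#' absent from the table.
#'
#' @param ld An [ld_info()] object.
#' @param a,b Variant IDs (recycled to common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "LDInfo"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) {
      out[i] <- 1
    } else {
      out[i] <- get0(key[i], envir = ld$index, ifnotfound = 0)
    }
  }
  out
}

#' @export
print.LDInfo <- function(x, ...) {
  cat(sprintf("LDInfo: %d pairs (panel: %s)\n", nrow(x$pairs),
              x$panel_label))
  invisible(x)
}
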