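# Internal helpers shared across modules.

# Deterministic derivation of child seeds from one root seed, by counter.
# Keeps every derived value inside [1, 2^31 - 2] so set.seed() never sees a
# value that overflows R's 32-bit integers.
derive_seed <- function(root, counter) {
  stopifnot(is.numeric(root), length(root) == 1L,
            is.numeric(counter), length(counter) == 1L)
  x <- (abs(as.double(root)) %% 2147483647) + 1
  x <- (x * 48271 + as.double(counter)) %% 2147483647
  as.integer(x + 1)
}

# Number formatting used for every table the package writes: 17 significant
# digits guarantees doubles survive a write/read round trip bit-identically.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(DNA_COMPLEMENT[a])

is_palindromic_pair <- function(a1, a2) a2 == unname(DNA_COMPLEMENT[a1])
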