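# Internal helpers: reverse complement, RNG stream derivation, content hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`; accepts A/C/G/T/N (uppercase).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Derive a per-stage RNG seed from the master seed, so that editing one
# stage's parameters does not perturb another stage's draws. Kept < 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, nchar(stage) > 0)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) + h * 2654435 + 97) %% 2147483647)
}

# Small rolling hash over a character scalar (manifest/config identity only).
content_hash <- function(x) {
  stopifnot(is.character(x))
  x <- paste(x, collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Hash a file's bytes (used in run manifests).
file_hash <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  h <- 5381
  # fold in chunks to keep the R loop short
  ints <- as.integer(raw)
  for (i in seq(1, length(ints), by = 4096)) {
    chunk <- ints[i:min(i + 4095, length(ints))]
    h <- (h * 33 + sum(chunk * seq_along(chunk)) %% 2147483647) %% 2147483647
  }
  sprintf("%08x:%d", as.integer(h), length(ints))
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s must contain only %s (got: %s)", what,
                 if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                 substr(x[bad][1], 1, 30)), call. = FALSE)
  }
  invisible(x)
}

is_probability <- function(p) is.numeric(p) && all(p >= 0 & p <= 1)

#' Pairwise mismatch counts between DNA strings
#'
#' Compares `a[i]` against `b[i]` (or a scalar `b`) over the first
#' `min(nchar)` positions; positions where either string holds a non-ACGT
#' character (for example consensus `N`) are skipped. Used for error-rate
#' measurements against ground truth.
#'
#' @param a,b character vectors of DNA strings (`b` may be scalar).
#' @return list with integer vectors `mismatches` and `compared`.
#' @export
mismatch_counts <- function(a, b) mismatch_counts_cpp(a, b)
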