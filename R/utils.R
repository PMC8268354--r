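#' @importFrom stats rnorm runif pchisq oneway.test dhyper setNames
#' @importFrom utils head tail write.table read.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the simulator and the
#' probe counter; IUPAC ambiguity codes other than N are not supported.
#'
#' @param x character vector of DNA strings (A/C/G/T/N, either case).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(toupper(comp), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' Random DNA string (uses the current RNG state)
#' @param n length in bases.
#' @return single DNA string.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Deterministic sub-stream seed: every generator op draws its own stream from
# (run seed, op tag) so outputs are reproducible independently of call order.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) %% 65011) * 33013 + h %% 32749)
}

# run fn with a local seed, leaving the caller's RNG untouched
with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
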