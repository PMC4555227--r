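# Shared internal helpers.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()];
#' IUPAC ambiguity codes (including `N`) are handled.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("CCGGAAGT", "ACGT"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# error unless every string is non-empty [ACGT]+ (optionally allowing N)
assert_dna <- function(x, allow_n = FALSE, what = "sequence") {
  if (length(x) == 0L || any(is.na(x)) || any(!nzchar(x))) {
    abort(sprintf("%s must be a non-empty DNA string", what))
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-DNA characters: %s", what,
      paste(unique(x[bad])[seq_len(min(3, sum(bad)))], collapse = ", ")
    ))
  }
  invisible(x)
}

# split strings into a character matrix (rows = strings); all equal length
seq_char_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L) abort("sequences must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

# evaluate expr under a fixed seed without touching the caller's RNG;
# seed = NULL means use the current RNG stream
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# hamming distance between one string and a vector of equal-length strings
hamming_to <- function(x, targets) {
  tc <- strsplit(targets, "", fixed = TRUE)
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(tc, function(t) sum(t != xc), integer(1))
}

# sub-seeds for pipeline stages, kept inside 32-bit integer range
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
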