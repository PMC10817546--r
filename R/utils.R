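DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences over A/C/G/T (N allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random sequence of length n over ACGT (uses the current RNG stream).
random_seq <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability `rate`, drawing the new
# base uniformly from the three alternatives. Returns the mutated string.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES4, b), 1L)
    }, character(1))
  }
  paste(bases, collapse = "")
}

# Stop unless sequences are non-empty strings over the DNA alphabet.
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || any(is.na(x)) || any(nchar(x) == 0L))
    stop(what, " must be non-empty character strings")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop(what, " contains non-ACGTN characters")
  invisible(x)
}

# Phred+33 encoding helpers.
phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L, multiple = FALSE)
}
char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Expected number of sequencing errors implied by Phred qualities
#'
#' E = sum over bases of 10^(-Q/10).
#'
#' @param quals Integer vector of Phred quality scores.
#' @return Non-negative number.
#' @export
expected_errors <- function(quals) {
  sum(10^(-quals / 10))
}

# Deterministic sub-seed derivation: combine a base seed with a stream tag,
# staying well inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + (as.integer(tag) %% 997L)
}
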