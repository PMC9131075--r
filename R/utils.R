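#' Round half away from zero
#'
#' Rounding used for all reported percentages, so that e.g. 18.665 becomes
#' 18.67 rather than banker's-rounded 18.66.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimal places (default 2, matching summary-table convention)
#' @return percentage, rounded half-up; 0 when the denominator is 0
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_up(100 * num / den, digits)
  out[rep_len(den == 0, length(out))] <- 0
  out
}

#' Unweighted mean of per-genotype percentages
#'
#' Cross-genotype "averages" are means of the per-genotype percentages, not
#' pooled counts.
#'
#' @param x vector of percentages
#' @param digits decimal places
#' @return mean percentage, rounded half-up
#' @export
mean_pct <- function(x, digits = 2) {
  round_half_up(mean(x), digits)
}

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Translate coding sequences
#'
#' Standard-code translation; a trailing stop codon is trimmed.
#'
#' @param cds character vector of CDS strings (lengths divisible by 3)
#' @return character vector of protein strings
#' @export
translate_cds <- function(cds) {
  if (length(cds) == 0) return(character(0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), if.fuzzy.codon = "X"
  ))
  unname(sub("\\*$", "", aa))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings
#' @return reverse-complemented character vector
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

# Random DNA of given length from a uniform base composition.
random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Split a CDS string into its codons.
split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# Stable integer sub-seed derived from a master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
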