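# Shared small helpers. All internal coordinates in this package are
# 0-based half-open [start, end); printed output is 1-based inclusive.

#' Round half away from zero
#'
#' Plain decimal rounding where exact halves round up (`round_half_up(0.5)`
#' is 1, `round_half_up(86.75, 1)` is 86.8). Used for all reported
#' percentages and means so that printed summaries match conventional
#' manuscript rounding rather than IEEE banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total
#'
#' @param n count (numerator)
#' @param total denominator, must be > 0
#' @param digits decimal places (default 0, i.e. whole percent)
#' @return `100 * n / total`, rounded half-up
#' @export
percent_of <- function(n, total, digits = 0) {
  stopifnot(is.numeric(n), is.numeric(total))
  if (any(total <= 0)) stop("percent_of(): total must be positive")
  round_half_up(100 * n / total, digits)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of ACGTN sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# GC percentage of a primer-sized sequence (plain character string)
gc_percent <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)
  vapply(v, function(ch) 100 * sum(ch %in% c("G", "C")) / length(ch), 0)
}

# split a string into a character vector of single bases
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_scalar_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

# stable derived seed below 2^31 for per-scaffold streams
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1000L + as.integer(i) %% 1000L
}
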