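#' Round half away from zero
#'
#' Reporting convention for physical sizes: ties round away from zero
#' (so 0.25 -> 0.3 at one decimal), unlike R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# coerce character / DNAString / DNAStringSet element to a single upper-case
# character sequence
.as_seq_chr <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
  toupper(x)
}

.as_dna <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(.as_seq_chr(x))
}

# random DNA with a target AT fraction (A,T each at/2; C,G each (1-at)/2)
.rand_dna_chr <- function(n, at_fraction) {
  if (n == 0L) return("")
  p <- c(at_fraction / 2, (1 - at_fraction) / 2, (1 - at_fraction) / 2,
         at_fraction / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x))
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}

.stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  invisible(as.numeric(x))
}
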