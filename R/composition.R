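#' AT content of a sequence
#'
#' Fraction (A + T) / (A + C + G + T); ambiguity (N) positions are excluded
#' from numerator and denominator.
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @return fraction in \[0, 1\]
#' @examples
#' at_content("ATAT")  # 1
#' @export
at_content <- function(seq) {
  s <- .as_dna(seq)
  cnt <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  tot <- sum(cnt)
  if (tot == 0L)
    stop("sequence has no unambiguous bases", call. = FALSE)
  unname((cnt[["A"]] + cnt[["T"]]) / tot)
}

#' Strand asymmetry indices
#'
#' Ratios of complementary base counts on the given strand, each reported as
#' `max(x/y, y/x)` so a value of 1 means perfect balance: max A/T, max C/G,
#' and max purine/pyrimidine ((A+G) vs (C+T)). A zero denominator against a
#' nonzero numerator yields `Inf`; two zero counts are reported as 1.
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @return named numeric vector `c(max_at, max_cg, max_pupy)`
#' @examples
#' strand_asymmetry("AAAT")["max_at"]  # 3
#' @export
strand_asymmetry <- function(seq) {
  s <- .as_dna(seq)
  if (length(s) == 0L) stop("sequence must be non-empty", call. = FALSE)
  cnt <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  ratio_max <- function(x, y) {
    if (x == 0 && y == 0) return(1)
    if (x == 0 || y == 0) return(Inf)
    max(x / y, y / x)
  }
  c(max_at = ratio_max(cnt[["A"]], cnt[["T"]]),
    max_cg = ratio_max(cnt[["C"]], cnt[["G"]]),
    max_pupy = ratio_max(cnt[["A"]] + cnt[["G"]], cnt[["C"]] + cnt[["T"]]))
}

# strand-symmetrized k-mer counts; circular counting appends the first k-1
# bases so every rotation of a monomer yields identical counts
.kmer_counts_sym <- function(seq, k, circular = TRUE) {
  s <- .as_dna(seq)
  one <- function(x) {
    if (circular && length(x) >= k && k > 1L)
      x <- Biostrings::xscat(x, Biostrings::subseq(x, 1L, k - 1L))
    Biostrings::oligonucleotideFrequency(x, k)
  }
  one(s) + one(Biostrings::reverseComplement(s))
}

.freq <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) counts else counts / tot
}

#' Dinucleotide relative abundances (rho*)
#'
#' Karlin-style dinucleotide signature rho*(XY) = f*(XY) / (f*(X) f*(Y)),
#' computed on strand-symmetrized frequencies (the sequence pooled with its
#' reverse complement). Monomers are treated as circular so the statistic is
#' invariant to the arbitrary rotation at which a tandem-repeat consensus is
#' written. Values near 1 indicate neutral representation; dinucleotides
#' absent from the data get 0.
#'
#' @param seq DNA sequence of length >= 2
#' @param circular treat the sequence as circular (default `TRUE`; use
#'   `FALSE` for linear fragments such as reads)
#' @return named numeric vector of 16 ratios
#' @export
dinucleotide_rho <- function(seq, circular = TRUE) {
  s <- .as_dna(seq)
  if (length(s) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  .rho_from_counts(.kmer_counts_sym(s, 1L), .kmer_counts_sym(s, 2L, circular))
}

.rho_from_counts <- function(c1, c2) {
  f1 <- .freq(c1)
  f2 <- .freq(c2)
  bases <- names(f1)
  out <- setNames(numeric(length(f2)), names(f2))
  for (d in names(f2)) {
    x <- substr(d, 1L, 1L); y <- substr(d, 2L, 2L)
    if (f2[d] > 0) out[d] <- f2[d] / (f1[x] * f1[y])
  }
  out
}

#' Trinucleotide relative abundances (gamma*)
#'
#' Third-order representation statistic
#' `gamma*(XYZ) = f*(XYZ) f*(X) f*(Y) f*(Z) / (f*(XY) f*(YZ) f*(XnZ))`,
#' where `f*(XnZ)` is the frequency of X and Z separated by one arbitrary
#' base; all frequencies strand-symmetrized, and circular for monomers.
#' Trinucleotides absent from the data get 0.
#'
#' @inheritParams dinucleotide_rho
#' @param seq DNA sequence of length >= 3
#' @return named numeric vector of 64 ratios
#' @export
trinucleotide_gamma <- function(seq, circular = TRUE) {
  s <- .as_dna(seq)
  if (length(s) < 3L) stop("sequence must have length >= 3", call. = FALSE)
  .gamma_from_counts(.kmer_counts_sym(s, 1L),
                     .kmer_counts_sym(s, 2L, circular),
                     .kmer_counts_sym(s, 3L, circular))
}

.gamma_from_counts <- function(c1, c2, c3) {
  f1 <- .freq(c1)
  f2 <- .freq(c2)
  f3 <- .freq(c3)
  # gapped pair frequency f(XnZ): sum the 3-mer frequencies over the middle base
  fg <- matrix(0, 4, 4, dimnames = list(names(f1), names(f1)))
  for (t in names(f3))
    fg[substr(t, 1, 1), substr(t, 3, 3)] <-
      fg[substr(t, 1, 1), substr(t, 3, 3)] + f3[t]
  out <- setNames(numeric(length(f3)), names(f3))
  for (t in names(f3)) {
    if (f3[t] == 0) next
    x <- substr(t, 1, 1); y <- substr(t, 2, 2); z <- substr(t, 3, 3)
    den <- f2[paste0(x, y)] * f2[paste0(y, z)] * fg[x, z]
    out[t] <- if (den > 0) f3[t] * f1[x] * f1[y] * f1[z] / den else 0
  }
  out
}

#' Full composition profile of a sequence
#'
#' @inheritParams dinucleotide_rho
#' @return an object of class `composition_profile`: list with `at_fraction`,
#'   `max_at`, `max_cg`, `max_pupy`, `rho` (16 values), `gamma` (64 values)
#' @export
composition_profile <- function(seq, circular = TRUE) {
  s <- .as_dna(seq)
  asym <- strand_asymmetry(s)
  structure(list(at_fraction = at_content(s),
                 max_at = unname(asym["max_at"]),
                 max_cg = unname(asym["max_cg"]),
                 max_pupy = unname(asym["max_pupy"]),
                 rho = dinucleotide_rho(s, circular),
                 gamma = trinucleotide_gamma(s, circular)),
            class = "composition_profile")
}

#' Composition profile of an unassembled read pool
#'
#' Reads are first oriented to the reference strand (each read is kept or
#' reverse-complemented according to which strand scores higher against the
#' orientation reference under the local-alignment scoring), then base and
#' k-mer counts are pooled over the oriented reads (linear counting) and the
#' per-sequence formulas applied.
#'
#' @param reads a `DNAStringSet`/`QualityScaledDNAStringSet` or character
#'   vector of reads
#' @param orientation_reference consensus sequence defining the strand
#' @param params an [align_params()] used for orientation scoring
#' @return a `composition_profile`
#' @export
pool_composition <- function(reads, orientation_reference,
                             params = align_params()) {
  seqs <- if (is(reads, "XStringSet")) as.character(reads) else toupper(reads)
  if (length(seqs) == 0L) stop("read pool is empty", call. = FALSE)
  ref <- .as_seq_chr(orientation_reference)
  fwd <- .sw_scores_cpp(seqs, ref, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  rev <- .sw_scores_cpp(seqs, .revcomp_chr(ref), params$match,
                        params$mismatch, params$gap_open, params$gap_extend)
  flip <- rev > fwd
  if (any(flip))
    seqs[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
  pool <- Biostrings::DNAStringSet(seqs)
  cnt1 <- colSums(Biostrings::oligonucleotideFrequency(pool, 1L))
  csym <- function(k) {
    colSums(Biostrings::oligonucleotideFrequency(pool, k)) +
      colSums(Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(pool), k))
  }
  asym <- {
    ratio_max <- function(x, y) {
      if (x == 0 && y == 0) 1 else if (x == 0 || y == 0) Inf
      else max(x / y, y / x)
    }
    c(max_at = ratio_max(cnt1["A"], cnt1["T"]),
      max_cg = ratio_max(cnt1["C"], cnt1["G"]),
      max_pupy = ratio_max(cnt1["A"] + cnt1["G"], cnt1["C"] + cnt1["T"]))
  }
  structure(list(at_fraction = unname((cnt1["A"] + cnt1["T"]) / sum(cnt1)),
                 max_at = unname(asym["max_at"]),
                 max_cg = unname(asym["max_cg"]),
                 max_pupy = unname(asym["max_pupy"]),
                 rho = .rho_from_counts(csym(1L), csym(2L)),
                 gamma = .gamma_from_counts(csym(1L), csym(2L), csym(3L))),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: AT %.3f | max A/T %.2f | max C/G %.2f | max Pu/Py %.2f\n",
              x$at_fraction, x$max_at, x$max_cg, x$max_pupy))
  cat("rho* range:", sprintf("%.2f-%.2f", min(x$rho[x$rho > 0]),
                             max(x$rho)), "\n")
  invisible(x)
}
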