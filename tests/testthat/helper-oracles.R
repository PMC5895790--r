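# Independent oracles used across the test files. These deliberately share no
# code with the package: the alignment oracle is a literal three-matrix
# dynamic program in plain R, and the trinucleotide oracle counts k-mers by
# substring enumeration.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force affine-gap Smith-Waterman: H/E/F matrices, gap of length k
# costs gap_open + k * gap_extend
sw_oracle <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  F <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      sub <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# literal re-implementation of the strand-symmetrized (optionally circular)
# k-mer frequencies and the trinucleotide relative-abundance formula
# gamma(XYZ) = f(XYZ) f(X) f(Y) f(Z) / (f(XY) f(YZ) f(XnZ))
kmer_freq_oracle <- function(seq, k, circular = TRUE) {
  count_one <- function(s) {
    if (circular && k > 1) s <- paste0(s, substr(s, 1, k - 1))
    n <- nchar(s) - k + 1
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1)
    table(factor(kmers, levels = apply(
      expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
      1, paste, collapse = "")))
  }
  cnt <- count_one(seq) + count_one(revcomp_chr(seq))
  as.numeric(cnt) -> v
  names(v) <- names(cnt)
  v / sum(v)
}

gamma_oracle <- function(seq, circular = TRUE) {
  f1 <- kmer_freq_oracle(seq, 1, circular)
  f2 <- kmer_freq_oracle(seq, 2, circular)
  f3 <- kmer_freq_oracle(seq, 3, circular)
  out <- setNames(numeric(length(f3)), names(f3))
  for (t in names(f3)) {
    if (f3[t] == 0) next
    x <- substr(t, 1, 1); y <- substr(t, 2, 2); z <- substr(t, 3, 3)
    fxnz <- sum(f3[substr(names(f3), 1, 1) == x &
                   substr(names(f3), 3, 3) == z])
    den <- f2[paste0(x, y)] * f2[paste0(y, z)] * fxnz
    out[t] <- if (den > 0) f3[t] * f1[x] * f1[y] * f1[z] / den else 0
  }
  out
}

# minimal read_assignment object for table-level tests with constructed counts
fake_assignment <- function(counts, total = sum(counts), unassigned = total - sum(counts)) {
  structure(list(
    assignments = data.frame(read_id = character(0), family = character(0),
                             score = integer(0)),
    counts = counts, total = total, unassigned = unassigned, ties = 0L),
    class = "read_assignment")
}

# constant-quality read set from plain sequences
qreads <- function(seqs, q = 30L, ids = sprintf("r%03d", seq_along(seqs))) {
  quals <- vapply(nchar(seqs), function(w)
    strrep(rawToChar(as.raw(q + 33L)), w), "")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
}

# read set with explicit per-read integer quality vectors
qreads_explicit <- function(seqs, qual_ints, ids = sprintf("r%03d", seq_along(seqs))) {
  quals <- vapply(qual_ints, function(qv)
    rawToChar(as.raw(qv + 33L)), "")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
}
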