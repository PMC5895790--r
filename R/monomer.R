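#' Estimate the tandem period of an array sequence
#'
#' Shifted-identity (match autocorrelation) period estimator: for each lag in
#' `[min_period, max_period]` the fraction of positions at which the sequence
#' matches itself shifted by the lag is computed; the reported period is the
#' smallest lag whose match fraction exceeds `min_identity` and is a local
#' maximum. Returns the monomer length of a clean head-to-tail array, never a
#' multiple of it, and is invariant to the rotation at which the array starts.
#'
#' @param array_seq DNA sequence of a (putative) tandem array
#' @param min_period,max_period search window in bp; `max_period` defaults to
#'   half the sequence length
#' @param min_identity match-fraction threshold a lag must exceed (default 0.8,
#'   i.e. up to ~10% per-copy divergence is tolerated)
#' @return list with `period` and `confidence` (the match fraction at the
#'   period), or `NULL` when no lag qualifies
#' @export
estimate_period <- function(array_seq, min_period = 1L, max_period = NULL,
                            min_identity = 0.8) {
  s <- charToRaw(.as_seq_chr(array_seq))
  L <- length(s)
  min_period <- .stopifnot_scalar_int(min_period, "min_period", 1L)
  if (L < 2L * min_period)
    stop("sequence too short for the requested period window", call. = FALSE)
  if (is.null(max_period)) max_period <- L %/% 2L
  max_period <- .stopifnot_scalar_int(max_period, "max_period", min_period)
  if (max_period > L %/% 2L)
    stop("sequence too short for the requested period window", call. = FALSE)
  lags <- min_period:max_period
  frac <- vapply(lags, function(k)
    mean(s[seq_len(L - k)] == s[seq_len(L - k) + k]), 0)
  n <- length(frac)
  left <- c(-Inf, frac[-n])
  right <- c(frac[-1L], -Inf)
  ok <- frac > min_identity & frac >= left & frac >= right
  if (!any(ok)) return(NULL)
  i <- which(ok)[1L]
  list(period = lags[i], confidence = frac[i])
}

#' Detect internal subrepeats in a monomer (dot-plot analysis)
#'
#' Scans the self-comparison matrix for off-main-diagonal runs of exact
#' identity of length at least `min_len`: a run at lag `p` means the monomer
#' contains an internal repetition with period `p`. An empty result means the
#' monomer has no internal subrepeat structure (its length cannot be
#' explained by higher-order-repeat intermediates).
#'
#' @param monomer DNA sequence; must be at least `2 * min_len` long
#' @param min_len minimum identity run length to report (default 20)
#' @return data.frame with columns `period`, `start`, `end` (0-based,
#'   half-open span of the longest qualifying run at that lag), `length`;
#'   zero rows when no subrepeats are found
#' @export
detect_subrepeats <- function(monomer, min_len = 20L) {
  s <- charToRaw(.as_seq_chr(monomer))
  L <- length(s)
  min_len <- .stopifnot_scalar_int(min_len, "min_len", 1L)
  if (L < 2L * min_len)
    stop("monomer shorter than 2 * min_len", call. = FALSE)
  res <- list()
  for (lag in seq_len(L - min_len)) {
    eq <- s[seq_len(L - lag)] == s[seq_len(L - lag) + lag]
    r <- rle(eq)
    if (!any(r$values & r$lengths >= min_len)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    best <- hit[which.max(r$lengths[hit])]
    res[[length(res) + 1L]] <- data.frame(
      period = lag, start = starts[best] - 1L, end = ends[best],
      length = r$lengths[best])
  }
  if (length(res) == 0L)
    return(data.frame(period = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  do.call(rbind, res)
}

.gc_frac <- function(x) {
  n <- nchar(x)
  (n - nchar(gsub("[GC]", "", x))) / n
}

.wallace_tm <- function(x) {
  at <- nchar(gsub("[GC]", "", x))
  2 * at + 4 * (nchar(x) - at)
}

#' Design an outward-facing primer pair on a monomer
#'
#' Outward-facing primers point away from each other within one monomer, so
#' on genomic DNA they can amplify only across the junction between adjacent
#' tandem copies -- a logical assay for tandem organization. The forward
#' primer is placed near the monomer's 3' end reading toward increasing
#' coordinates; the reverse primer binds near the 5' end and reads toward
#' decreasing coordinates (geometry: `reverse$end <= forward$start`, 0-based
#' half-open). Sites are chosen with GC content in `gc_range` where the
#' (often AT-rich) monomer allows it, relaxing to `gc_floor` with a warning.
#'
#' @param monomer DNA sequence; must be at least `2 * max(lengths) + 1` bp
#' @param lengths admissible primer lengths (default 18:25)
#' @param gc_range preferred GC-content window (default 40-60%)
#' @param gc_floor relaxed minimum GC when no site meets `gc_range`
#' @return an object of class `primer_pair`: lists `forward` and `reverse`
#'   with `start`, `end` (site coordinates on the monomer, 0-based
#'   half-open), `seq` (primer 5'->3'), `gc`, `tm` (Wallace rule), plus a
#'   `relaxed` flag
#' @export
design_outward_primers <- function(monomer, lengths = 18:25,
                                   gc_range = c(0.4, 0.6), gc_floor = 0.3) {
  m <- .as_seq_chr(monomer)
  L <- nchar(m)
  if (L < 2L * max(lengths) + 1L)
    stop("no valid primer pair: monomer too short for outward geometry",
         call. = FALSE)
  half <- L %/% 2L
  candidates <- function(starts, len) {
    sites <- substring(m, starts, starts + len - 1L)
    data.frame(start = starts - 1L, end = starts - 1L + len, seq = sites,
               gc = .gc_frac(sites), stringsAsFactors = FALSE)
  }
  all_cand <- do.call(rbind, lapply(lengths, function(len)
    candidates(seq_len(L - len + 1L), len)))
  fwd_c <- all_cand[all_cand$start >= half, , drop = FALSE]
  rev_c <- all_cand[all_cand$end <= half, , drop = FALSE]
  pick <- function(cand, lo, hi, forward) {
    ok <- cand[cand$gc >= lo & cand$gc <= hi, , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
    # most outward site: forward as far 3' as possible, reverse as far 5'
    ok[if (forward) which.max(ok$start) else which.min(ok$end), , drop = FALSE]
  }
  relaxed <- FALSE
  f <- pick(fwd_c, gc_range[1], gc_range[2], TRUE)
  r <- pick(rev_c, gc_range[1], gc_range[2], FALSE)
  if (is.null(f) || is.null(r)) {
    relaxed <- TRUE
    warning("no site with GC in [", gc_range[1] * 100, ", ",
            gc_range[2] * 100, "]%; relaxing to GC >= ", gc_floor * 100,
            "% (AT-rich monomer)", call. = FALSE)
    if (is.null(f)) f <- pick(fwd_c, gc_floor, 1, TRUE)
    if (is.null(r)) r <- pick(rev_c, gc_floor, 1, FALSE)
  }
  if (is.null(f) || is.null(r))
    stop("no valid primer pair under relaxed constraints", call. = FALSE)
  mk <- function(site, primer_seq) {
    list(start = site$start, end = site$end, seq = primer_seq,
         gc = site$gc, tm = .wallace_tm(primer_seq))
  }
  structure(list(forward = mk(f, f$seq),
                 reverse = mk(r, .revcomp_chr(r$seq)),
                 relaxed = relaxed),
            class = "primer_pair")
}

#' In-silico PCR
#'
#' Exact-match primer-site scanning on both strands. A product runs from a
#' forward-primer site to the next downstream site whose plus-strand sequence
#' is the reverse complement of the reverse primer; both primer orientations
#' are scanned. On an n-copy head-to-tail array an outward-facing pair yields
#' exactly n - 1 junction products of equal length
#' `(monomer_length - forward$start) + reverse$end`; a single monomer yields
#' none.
#'
#' @param template DNA sequence
#' @param pair a [design_outward_primers()] result, or a list with `forward`
#'   and `reverse` primer sequences (plain character)
#' @param max_product maximum product length reported (default 5000)
#' @return sorted integer vector of product lengths (possibly empty)
#' @export
in_silico_pcr <- function(template, pair, max_product = 5000L) {
  t_dna <- .as_dna(template)
  p_fwd <- if (is.list(pair$forward)) pair$forward$seq else pair$forward
  p_rev <- if (is.list(pair$reverse)) pair$reverse$seq else pair$reverse
  if (nchar(p_fwd) < 15L || nchar(p_rev) < 15L)
    stop("primers must be at least 15 bp", call. = FALSE)
  scan <- function(left_primer, right_primer) {
    ls <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(left_primer), t_dna))
    re <- Biostrings::end(Biostrings::matchPattern(
      Biostrings::DNAString(.revcomp_chr(right_primer)), t_dna))
    if (length(ls) == 0L || length(re) == 0L) return(integer(0))
    re <- sort(re)
    out <- integer(0)
    for (s in ls) {
      nxt <- re[re >= s + nchar(left_primer)]
      if (length(nxt) == 0L) next
      len <- nxt[1L] - s + 1L
      if (len <= max_product) out <- c(out, len)
    }
    out
  }
  sort(c(scan(p_fwd, p_rev), scan(p_rev, p_fwd)))
}

#' Percent identity between two sequences
#'
#' Global alignment identity with free end gaps (overlap alignment) under the
#' package's alignment scoring: matches divided by alignment columns, times
#' 100. Used to compare cloned array sequences with their predicted
#' consensus.
#'
#' @param a,b DNA sequences
#' @param params an [align_params()] supplying the scoring scheme
#' @return percentage in \[0, 100\]
#' @export
percent_identity <- function(a, b, params = align_params()) {
  sa <- .as_seq_chr(a); sb <- .as_seq_chr(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "overlap", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}
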