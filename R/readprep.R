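#' Read trimming and quality-filter parameters
#'
#' Defaults reproduce a common pre-mapping protocol for 101-nt single-end
#' reads: drop the first base, truncate to 100 nt, and keep a read only if at
#' least 95 of its positions reach Phred 10.
#'
#' @param trim_to target read length after trimming (default 100)
#' @param drop_leading number of leading bases removed (default 1)
#' @param min_q Phred cutoff (default 10). By default a base passes when its
#'   quality is `>= min_q`; set `strict = TRUE` for a strictly-greater reading
#'   of the cutoff (affects boundary reads only).
#' @param min_bases_at_q minimum number of passing positions (default 95)
#' @param strict logical; count bases with quality strictly above `min_q`
#' @param offset quality encoding offset: 33 (Phred+33, default) or 64
#' @return an object of class `qc_params`
#' @export
qc_params <- function(trim_to = 100L, drop_leading = 1L, min_q = 10L,
                      min_bases_at_q = 95L, strict = FALSE, offset = 33L) {
  trim_to <- .stopifnot_scalar_int(trim_to, "trim_to", 1L)
  drop_leading <- .stopifnot_scalar_int(drop_leading, "drop_leading", 0L)
  min_q <- .stopifnot_scalar_int(min_q, "min_q", 0L)
  min_bases_at_q <- .stopifnot_scalar_int(min_bases_at_q, "min_bases_at_q", 0L)
  if (trim_to < min_bases_at_q)
    stop("`trim_to` must be >= `min_bases_at_q`", call. = FALSE)
  if (!offset %in% c(33L, 64L))
    stop("`offset` must be 33 or 64", call. = FALSE)
  structure(list(trim_to = trim_to, drop_leading = drop_leading,
                 min_q = min_q, min_bases_at_q = min_bases_at_q,
                 strict = isTRUE(strict), offset = as.integer(offset)),
            class = "qc_params")
}

#' Trim reads to a fixed length
#'
#' Removes `drop_leading` bases from the 5' end and truncates to `trim_to`
#' bases. Reads shorter than `trim_to` after trimming are discarded (the
#' uniform post-trim length keeps downstream proportion arithmetic exact).
#'
#' @param reads a `QualityScaledDNAStringSet`
#' @param params a [qc_params()]
#' @return list with `reads` (trimmed survivors) and `discarded` (count)
#' @export
trim_reads <- function(reads, params = qc_params()) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"),
            inherits(params, "qc_params"))
  w <- Biostrings::width(reads)
  keep <- w >= params$drop_leading + params$trim_to
  kept <- reads[keep]
  if (length(kept))
    kept <- IRanges::narrow(kept, start = params$drop_leading + 1L,
                               end = params$drop_leading + params$trim_to)
  list(reads = kept, discarded = sum(!keep))
}

#' Per-read quality filter
#'
#' A read passes when the number of positions whose Phred score reaches the
#' cutoff is at least `min_bases_at_q`.
#'
#' @param reads trimmed reads of uniform length
#' @param params a [qc_params()]
#' @return logical vector, `TRUE` for passing reads
#' @export
quality_filter <- function(reads, params = qc_params()) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"),
            inherits(params, "qc_params"))
  if (length(reads) == 0L) return(logical(0))
  q <- .quality_matrix(reads, params$offset)
  good <- if (params$strict) q > params$min_q else q >= params$min_q
  rowSums(good) >= params$min_bases_at_q
}

#' Trim and quality-filter a FASTQ read set
#'
#' @param input FASTQ path or a `QualityScaledDNAStringSet`
#' @param params a [qc_params()]
#' @param output optional path; when given, surviving reads are written there
#' @return list with `reads` (a `QualityScaledDNAStringSet`) and `summary`, a
#'   one-row data.frame with columns `reads_in`, `discarded_short`,
#'   `failed_quality`, `reads_out` (conserving
#'   `reads_in = reads_out + discarded_short + failed_quality`)
#' @export
process_fastq <- function(input, params = qc_params(), output = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  n_in <- length(reads)
  tr <- trim_reads(reads, params)
  pass <- quality_filter(tr$reads, params)
  out <- tr$reads[pass]
  summary <- data.frame(reads_in = n_in, discarded_short = tr$discarded,
                        failed_quality = sum(!pass), reads_out = length(out))
  if (!is.null(output)) write_fastq(out, output)
  list(reads = out, summary = summary)
}
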