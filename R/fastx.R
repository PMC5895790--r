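#' Read and write FASTA / FASTQ
#'
#' Thin wrappers around Biostrings I/O fixing the dialects used throughout the
#' package: FASTA wrapped at 60 columns, FASTQ with Phred+33 qualities carried
#' as a [Biostrings::QualityScaledDNAStringSet].
#'
#' @param path file path
#' @param x a `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ)
#' @return `read_fasta` a `DNAStringSet`; `read_fastq` a
#'   `QualityScaledDNAStringSet`; writers return `path` invisibly.
#' @name fastx
NULL

#' @rdname fastx
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' @rdname fastx
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 60L)
  invisible(path)
}

#' @rdname fastx
#' @export
read_fastq <- function(path) {
  out <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"),
      error = function(e) stop("malformed FASTQ `", path, "`: ",
                               conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qc <- tryCatch(as.character(Biostrings::quality(out)),
                 error = function(e) NULL)
  if (is.null(qc) || !identical(nchar(qc), Biostrings::width(out)))
    stop("malformed FASTQ `", path,
         "`: sequence and quality lengths differ", call. = FALSE)
  out
}

#' @rdname fastx
#' @export
write_fastq <- function(x, path) {
  stopifnot(is(x, "QualityScaledDNAStringSet"))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

# build a QualityScaledDNAStringSet from character sequences + integer
# phred values (constant per read or a list)
.make_qreads <- function(seqs, quals, ids) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  q <- Biostrings::PhredQuality(quals)
  Biostrings::QualityScaledDNAStringSet(dna, q)
}

# integer Phred matrix for uniform-width reads (fast path used by the QC
# filter); offset 33 for Phred+33, 64 for Phred+64
.quality_matrix <- function(reads, offset = 33L) {
  w <- unique(Biostrings::width(reads))
  if (length(w) != 1L)
    stop("reads must have uniform length for the quality matrix", call. = FALSE)
  if (length(reads) == 0L) return(matrix(integer(0), nrow = 0, ncol = w))
  qc <- as.character(Biostrings::quality(reads))
  matrix(utf8ToInt(paste(qc, collapse = "")) - as.integer(offset),
         ncol = w, byrow = TRUE)
}
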