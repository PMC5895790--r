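#' Local alignment scoring parameters
#'
#' BLASTn-style scoring used for read-to-repeat assignment: match +2,
#' mismatch -3, affine gaps costing `gap_open + k * gap_extend` for a gap of
#' length k, exact-word seeding of width `word_size`. The raw-score threshold
#' `min_score` (default 100, roughly 50 matched bases) stands in for an
#' E-value cutoff, whose calibration would depend on database size; at desk
#' scale a deterministic raw score is preferable.
#'
#' @param match match reward (> 0)
#' @param mismatch mismatch penalty (< 0)
#' @param gap_open,gap_extend affine gap costs (>= 0)
#' @param word_size exact-match seed width used to skip hopeless
#'   read/reference pairs; 0 disables seeding (every pair is aligned)
#' @param min_score minimum best score for a read to be assigned
#' @return an object of class `align_params`
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, word_size = 9L, min_score = 100L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 min_score = as.integer(min_score)),
            class = "align_params")
}

#' Smith-Waterman local alignment score
#'
#' Maximal local alignment score between two sequences under the affine-gap
#' scoring of [align_params()]. No low-complexity masking is ever applied:
#' satellite monomers are themselves low-complexity, and masking them would
#' destroy the analysis.
#'
#' @param read,ref DNA sequences (character or `DNAString`); non-ACGT bases
#'   never match
#' @param params an [align_params()]
#' @return integer score (>= 0)
#' @examples
#' local_align_score(strrep("ACGT", 25), strrep("ACGT", 25))  # 200
#' @export
local_align_score <- function(read, ref, params = align_params()) {
  a <- .as_seq_chr(read); b <- .as_seq_chr(ref)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  .sw_score_cpp(a, b, params$match, params$mismatch, params$gap_open,
                params$gap_extend)
}

#' Build a repeat reference set
#'
#' A reference set maps family names to one or more consensus/contig member
#' sequences; a read is scored against every member (and both strands) and a
#' family's score is the best over its members.
#'
#' @param x a named `DNAStringSet` or named character vector; duplicate names
#'   group multiple member sequences into one family. A FASTA path is also
#'   accepted.
#' @return an object of class `reference_set`
#' @export
reference_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    x <- read_fasta(x)
  seqs <- if (is(x, "DNAStringSet")) setNames(as.character(x), names(x))
          else vapply(x, .as_seq_chr, "")
  if (length(seqs) == 0L) stop("reference set is empty", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all reference sequences must be named", call. = FALSE)
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("reference sequences must be over A/C/G/T/N", call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("reference sequences must be non-empty", call. = FALSE)
  structure(list(seqs = seqs, families = sort(unique(names(seqs)))),
            class = "reference_set")
}

#' Assign reads to repeat families by best local alignment score
#'
#' Each read is mapped to at most one family: the one with the strictly
#' highest score over all member sequences and both strands, provided it
#' reaches `min_score`. Ties between families are broken toward the
#' lexicographically smallest family name and counted. Output rows are sorted
#' by read id, so the table is identical regardless of input read order.
#'
#' @param reads a `DNAStringSet`, `QualityScaledDNAStringSet`, or named
#'   character vector
#' @param refs a [reference_set()]
#' @param params an [align_params()]
#' @return an object of class `read_assignment`: list with `assignments`
#'   (data.frame: read_id, family (`NA` when unassigned), score), `counts`
#'   (named integer per family), `total`, `unassigned` and `ties`
#' @export
assign_reads <- function(reads, refs, params = align_params()) {
  stopifnot(inherits(refs, "reference_set"), inherits(params, "align_params"))
  seqs <- if (is(reads, "XStringSet")) setNames(as.character(reads),
                                                names(reads))
          else reads
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- sprintf("r%06d", seq_along(seqs))
  fams <- refs$families
  members <- c(refs$seqs,
               setNames(vapply(refs$seqs, .revcomp_chr, ""), names(refs$seqs)))
  fam_idx <- match(names(members), fams)
  res <- .assign_reads_cpp(unname(toupper(seqs)), unname(members), fam_idx,
                           length(fams), params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           params$word_size, params$min_score)
  df <- data.frame(read_id = names(seqs),
                   family = ifelse(res$family > 0L, fams[pmax(res$family, 1L)],
                                   NA_character_),
                   score = res$score, stringsAsFactors = FALSE)
  df <- df[order(df$read_id), , drop = FALSE]
  rownames(df) <- NULL
  counts <- setNames(integer(length(fams)), fams)
  tab <- table(df$family)
  counts[names(tab)] <- as.integer(tab)
  structure(list(assignments = df, counts = counts,
                 total = length(seqs), unassigned = sum(is.na(df$family)),
                 ties = sum(res$tie)),
            class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  cat("read_assignment:", x$total, "reads,", x$total - x$unassigned,
      "assigned to", length(x$counts), "families (", x$ties, "ties )\n")
  print(x$counts)
  invisible(x)
}

#' Genomic abundance table
#'
#' Converts per-family assigned-read counts into genome percentages and
#' physical sizes. The genome fraction is `count / total * 100` with `total`
#' the number of reads processed (assigned or not); physical size is
#' `fraction/100 * genome_size_mbp`, reported at one decimal
#' (half-away-from-zero).
#'
#' @param assignment a [assign_reads()] result
#' @param genome_size_mbp haploid genome size in Mbp (1C); e.g. 13410 for a
#'   13.41 Gbp genome
#' @return data.frame: family, count, pct_genome, mbp_1c
#' @export
abundance_table <- function(assignment, genome_size_mbp) {
  stopifnot(inherits(assignment, "read_assignment"))
  if (assignment$total <= 0L)
    stop("no reads in assignment table", call. = FALSE)
  stopifnot(genome_size_mbp > 0)
  pct <- assignment$counts / assignment$total * 100
  data.frame(family = names(assignment$counts),
             count = as.integer(assignment$counts),
             pct_genome = unname(pct),
             mbp_1c = unname(round_half_away(pct / 100 * genome_size_mbp, 1)),
             stringsAsFactors = FALSE)
}

#' Enrichment-calling parameters
#'
#' @param ratio_threshold ChIP/input ratio above which a family is called
#'   enriched (strict inequality; default 10)
#' @param min_genomic_proportion evaluation floor in percent of the genome
#'   (default 0.002); families below it are too sparse to evaluate reliably
#' @param evaluate_top_n only the `n` most abundant families (by input-pool
#'   counts) are evaluated (default 500)
#' @param denominator `"assigned"` (default) normalizes proportions by the
#'   assigned-read total of each pool; `"all"` uses all processed reads
#' @return an object of class `enrichment_params`
#' @export
enrichment_params <- function(ratio_threshold = 10,
                              min_genomic_proportion = 0.002,
                              evaluate_top_n = 500L,
                              denominator = c("assigned", "all")) {
  stopifnot(ratio_threshold > 0, min_genomic_proportion >= 0,
            evaluate_top_n >= 1)
  structure(list(ratio_threshold = ratio_threshold,
                 min_genomic_proportion = min_genomic_proportion,
                 evaluate_top_n = as.integer(evaluate_top_n),
                 denominator = match.arg(denominator)),
            class = "enrichment_params")
}

#' ChIP/input enrichment table
#'
#' Computes per-family normalized proportions in the ChIP and input pools,
#' their ratio, and the centromere-association call: a family is called when
#' its ratio strictly exceeds the threshold and its input-derived genomic
#' proportion reaches the evaluation floor. A family absent from the input
#' pool but present in the ChIP pool gets an infinite ratio and is called
#' only if the ChIP-pool proportion reaches the floor.
#'
#' @param chip,input [assign_reads()] results for the ChIP and input pools
#' @param params an [enrichment_params()]
#' @return data.frame: family, chip_count, input_count, chip_proportion,
#'   input_proportion, ratio, evaluated, call
#' @export
enrichment_table <- function(chip, input, params = enrichment_params()) {
  stopifnot(inherits(chip, "read_assignment"),
            inherits(input, "read_assignment"),
            inherits(params, "enrichment_params"))
  if (chip$total <= 0L || input$total <= 0L)
    stop("both pools must contain reads", call. = FALSE)
  fams <- sort(union(names(chip$counts), names(input$counts)))
  cc <- setNames(integer(length(fams)), fams)
  ic <- cc
  cc[names(chip$counts)] <- chip$counts
  ic[names(input$counts)] <- input$counts
  cden <- if (params$denominator == "assigned") sum(cc) else chip$total
  iden <- if (params$denominator == "assigned") sum(ic) else input$total
  if (cden == 0L || iden == 0L)
    stop("no assigned reads in one of the pools", call. = FALSE)
  cp <- cc / cden
  ip <- ic / iden
  ratio <- ifelse(ip > 0, cp / ip, ifelse(cp > 0, Inf, NA_real_))
  # genomic proportion (%) from the input pool (the pre-IP genome sample);
  # for zero-input families fall back to the ChIP pool
  gp <- ifelse(ic > 0, ic / input$total * 100, cc / chip$total * 100)
  rank_n <- rank(-ic, ties.method = "min")
  evaluated <- rank_n <= params$evaluate_top_n &
    gp >= params$min_genomic_proportion
  call <- evaluated & !is.na(ratio) & ratio > params$ratio_threshold
  data.frame(family = fams, chip_count = as.integer(cc),
             input_count = as.integer(ic), chip_proportion = unname(cp),
             input_proportion = unname(ip), ratio = unname(ratio),
             evaluated = unname(evaluated), call = unname(call),
             stringsAsFactors = FALSE)
}
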