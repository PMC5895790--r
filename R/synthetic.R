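#' Specify a synthetic satellite repeat family
#'
#' Describes one tandem-repeat family to be planted in a synthetic genome:
#' its monomer length and AT richness, the per-base divergence among array
#' copies, and the fraction of the genome the family should occupy. Defaults
#' emulate the ranges observed for plant satellite DNA: AT-rich monomers
#' (53-80% AT) from tens of bp up to ~2 kb, genomic fractions from below
#' 0.01% up to a few percent.
#'
#' @param name family identifier (unique within a genome spec)
#' @param monomer_length monomer size in bp (>= 1)
#' @param at_fraction target AT fraction of the monomer, in \[0, 1\]
#' @param divergence per-base substitution probability applied independently
#'   to each array copy, in \[0, 0.3\] (emulates the 92-99% copy-to-consensus
#'   identity typical of homogenized satellite arrays)
#' @param target_fraction fraction of the genome to occupy, in \[0, 1\]
#' @return an object of class `satellite_family`
#' @examples
#' satellite_family("satA", 191, at_fraction = 0.75, divergence = 0.05,
#'                  target_fraction = 0.027)
#' @export
satellite_family <- function(name, monomer_length, at_fraction = 0.7,
                             divergence = 0.05, target_fraction = 0.01) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  monomer_length <- .stopifnot_scalar_int(monomer_length, "monomer_length", 1L)
  .stopifnot_fraction(at_fraction, "at_fraction")
  .stopifnot_fraction(target_fraction, "target_fraction")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.3)
    stop("`divergence` must be in [0, 0.3]", call. = FALSE)
  structure(list(name = name, monomer_length = monomer_length,
                 at_fraction = at_fraction, divergence = divergence,
                 target_fraction = target_fraction),
            class = "satellite_family")
}

#' Specify a synthetic genome
#'
#' @param genome_length total genome length in bp
#' @param families list of [satellite_family()] objects with unique names whose
#'   `target_fraction`s sum to at most 1
#' @param background_at AT fraction of the non-repetitive filler sequence
#' @param seed integer seed; a fixed seed makes [build_genome()] bit-identical
#' @return an object of class `genome_spec`
#' @export
genome_spec <- function(genome_length, families, background_at = 0.6,
                        seed = 1L) {
  genome_length <- .stopifnot_scalar_int(genome_length, "genome_length", 1L)
  if (inherits(families, "satellite_family")) families <- list(families)
  stopifnot(length(families) > 0,
            all(vapply(families, inherits, TRUE, "satellite_family")))
  nms <- vapply(families, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("family names must be unique", call. = FALSE)
  tf <- vapply(families, `[[`, 0, "target_fraction")
  if (sum(tf) > 1 + 1e-12)
    stop("family target fractions sum to more than 1", call. = FALSE)
  .stopifnot_fraction(background_at, "background_at")
  structure(list(genome_length = genome_length, families = families,
                 background_at = background_at, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Quality model for simulated reads
#'
#' Constant Phred qualities by default; the `low_tail` mode degrades the 3'
#' tail of a random subset of reads to exercise the quality filter.
#'
#' @param type `"constant"` or `"low_tail"`
#' @param q Phred score of ordinary bases
#' @param low_q Phred score of degraded tail bases
#' @param tail_len number of 3' bases degraded in a low-quality read
#' @param prob_low probability that a read receives a degraded tail
#' @return an object of class `quality_model`
#' @export
quality_model <- function(type = c("constant", "low_tail"), q = 30L,
                          low_q = 2L, tail_len = 10L, prob_low = 0.1) {
  type <- match.arg(type)
  structure(list(type = type, q = as.integer(q), low_q = as.integer(low_q),
                 tail_len = as.integer(tail_len), prob_low = prob_low),
            class = "quality_model")
}

#' Generate a random monomer sequence
#'
#' @param length monomer length in bp (>= 1)
#' @param at_fraction expected AT fraction (A and T equiprobable, likewise C/G)
#' @param seed integer seed (deterministic output)
#' @return a [Biostrings::DNAString] of exactly `length` bases
#' @examples
#' make_monomer(50, 0.7, seed = 1)
#' @export
make_monomer <- function(length, at_fraction, seed = 1L) {
  length <- .stopifnot_scalar_int(length, "length", 1L)
  .stopifnot_fraction(at_fraction, "at_fraction")
  withr::with_seed(seed,
    Biostrings::DNAString(.rand_dna_chr(length, at_fraction)))
}

# substitute bases at `rate` per position; substitutions always change the base
.mutate_chr <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0L) return(x)
  r <- charToRaw(x)
  idx <- which(runif(length(r)) < rate)
  if (length(idx) == 0L) return(x)
  bases <- charToRaw("ACGT")
  code <- match(r[idx], bases) - 1L            # 0..3
  new_code <- (code + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  r[idx] <- bases[new_code + 1L]
  rawToChar(r)
}

#' Build a synthetic genome with planted tandem arrays
#'
#' Each family is laid down as one uninterrupted head-to-tail array of
#' independently mutated monomer copies; the copy number is the nearest whole
#' number of monomers to `target_fraction * genome_length`. Arrays are placed
#' in family order, separated by random-composition background filler.
#' Coordinates are 0-based, half-open.
#'
#' @param spec a [genome_spec()]
#' @return a list with elements `genome` (a named `DNAStringSet` of length 1)
#'   and `truth` (class `synthetic_truth`: array coordinates, exact planted
#'   fractions recomputable from the coordinates, and the unmutated consensus
#'   monomers usable as assignment references)
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$genome_length
    fams <- spec$families
    nms <- vapply(fams, `[[`, "", "name")
    monomers <- character(length(fams))
    arrays <- character(length(fams))
    alen <- integer(length(fams))
    ncop <- integer(length(fams))
    for (i in seq_along(fams)) {
      f <- fams[[i]]
      monomers[i] <- .rand_dna_chr(f$monomer_length, f$at_fraction)
      n <- as.integer(round(f$target_fraction * L / f$monomer_length))
      if (f$target_fraction > 0 && n < 1L) n <- 1L
      ncop[i] <- n
      if (n > 0L) {
        arr <- strrep(monomers[i], n)
        arrays[i] <- .mutate_chr(arr, f$divergence)
      } else arrays[i] <- ""
      alen[i] <- nchar(arrays[i])
    }
    total_arr <- sum(alen)
    if (total_arr > L)
      stop("planted arrays (", total_arr, " bp) exceed genome_length (", L,
           " bp); family fractions are infeasible", call. = FALSE)
    k <- length(fams)
    bg_total <- L - total_arr
    gaps <- if (bg_total > 0)
      as.vector(stats::rmultinom(1L, bg_total, rep(1, k + 1L)))
    else rep(0L, k + 1L)
    pieces <- character(2L * k + 1L)
    starts <- ends <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pieces[2L * i - 1L] <- .rand_dna_chr(gaps[i], spec$background_at)
      pos <- pos + gaps[i]
      starts[i] <- pos
      pieces[2L * i] <- arrays[i]
      pos <- pos + alen[i]
      ends[i] <- pos
    }
    pieces[2L * k + 1L] <- .rand_dna_chr(gaps[k + 1L], spec$background_at)
    genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- "chr1"
    truth <- structure(list(
      arrays = data.frame(family = nms, start = starts, end = ends,
                          monomer_length = vapply(fams, `[[`, 0L,
                                                  "monomer_length"),
                          n_copies = ncop, stringsAsFactors = FALSE),
      fractions = setNames((ends - starts) / L, nms),
      monomers = setNames(Biostrings::DNAStringSet(monomers), nms),
      genome_length = L), class = "synthetic_truth")
    list(genome = genome, truth = truth)
  })
}

#' Recompute planted fractions from array coordinates
#'
#' @param truth a `synthetic_truth` object
#' @return named numeric vector of per-family genomic fractions
#' @export
truth_fractions <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with(truth$arrays, setNames((end - start) / truth$genome_length, family))
}

#' Reference contigs from planted monomers
#'
#' Builds assignment references from a synthetic truth by concatenating each
#' family's consensus monomer head-to-tail until the contig reaches
#' `min_length`. Mapping references should be at least as long as a read:
#' against a bare short monomer a read's best local score is capped at
#' 2 x monomer length, which starves short-monomer families of assignments.
#'
#' @param truth a `synthetic_truth` from [build_genome()]
#' @param min_length minimum contig length in bp (default 202, twice the
#'   default read length)
#' @return a named `DNAStringSet`, one contig per family
#' @export
truth_references <- function(truth, min_length = 202L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mono <- as.character(truth$monomers)
  reps <- pmax(1L, ceiling(min_length / nchar(mono)))
  setNames(Biostrings::DNAStringSet(strrep(mono, reps)), names(mono))
}

#' Write the planted truth as TSV
#'
#' @param truth a `synthetic_truth` object
#' @param path output path
#' @param enrichment optional named enrichment factors to include
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path, enrichment = NULL) {
  df <- truth$arrays
  df$fraction <- truth_fractions(truth)[df$family]
  df$enrichment <- if (is.null(enrichment)) NA_real_
                   else unname(enrichment[df$family])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# qualities for n reads of width rl under a quality model (character vector)
.make_quals <- function(n, rl, qm) {
  if (n == 0L) return(character(0))
  base <- strrep(rawToChar(as.raw(qm$q + 33L)), rl)
  out <- rep(base, n)
  if (qm$type == "low_tail" && qm$tail_len > 0L) {
    hit <- which(runif(n) < qm$prob_low)
    if (length(hit)) {
      tl <- min(qm$tail_len, rl)
      degraded <- paste0(strrep(rawToChar(as.raw(qm$q + 33L)), rl - tl),
                         strrep(rawToChar(as.raw(qm$low_q + 33L)), tl))
      out[hit] <- degraded
    }
  }
  out
}

# extract reads at 1-based starts, reverse-complement where strand == "-",
# apply substitution errors
.reads_from_positions <- function(genome_chr, starts1, strand, rl, error_rate) {
  n <- length(starts1)
  if (n == 0L) return(character(0))
  seqs <- substring(genome_chr, starts1, starts1 + rl - 1L)
  rev <- strand == "-"
  if (any(rev))
    seqs[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev])))
  if (error_rate > 0) {
    all <- .mutate_chr(paste(seqs, collapse = ""), error_rate)
    seqs <- substring(all, (seq_len(n) - 1L) * rl + 1L, seq_len(n) * rl)
  }
  seqs
}

#' Simulate single-end shotgun reads from a genome
#'
#' Uniform start positions, both strands equiprobable, independent per-base
#' substitution errors, Phred+33 qualities from a [quality_model()]. Read
#' names encode the 0-based start and strand (`r000001:1234:+`) so that truth
#' accounting can label each read by its start position.
#'
#' @param genome a `DNAStringSet` of length 1 (as from [build_genome()]) or a
#'   `DNAString`
#' @param n_reads number of reads (>= 0)
#' @param read_length read length in bp (default 101, the common single-end
#'   Illumina mode for this kind of survey)
#' @param error_rate per-base substitution error probability
#' @param seed integer seed
#' @param qualities a [quality_model()]
#' @return a `QualityScaledDNAStringSet`
#' @export
simulate_reads <- function(genome, n_reads, read_length = 101L,
                           error_rate = 0, seed = 1L,
                           qualities = quality_model()) {
  n_reads <- .stopifnot_scalar_int(n_reads, "n_reads", 0L)
  read_length <- .stopifnot_scalar_int(read_length, "read_length", 1L)
  g <- if (is(genome, "DNAStringSet")) genome[[1L]] else .as_dna(genome)
  L <- length(g)
  if (read_length > L)
    stop("read_length exceeds genome length", call. = FALSE)
  gchr <- as.character(g)
  withr::with_seed(seed, {
    starts1 <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs <- .reads_from_positions(gchr, starts1, strand, read_length,
                                  error_rate)
    quals <- .make_quals(n_reads, read_length, qualities)
    ids <- sprintf("r%06d:%d:%s", seq_len(n_reads), starts1 - 1L, strand)
    .make_qreads(seqs, quals, ids)
  })
}

#' Parse 0-based start positions from simulated read names
#'
#' @param reads reads produced by [simulate_reads()] or [simulate_chip()]
#' @return integer vector of 0-based start positions
#' @export
read_start_positions <- function(reads) {
  as.integer(vapply(strsplit(names(reads), ":", fixed = TRUE), `[[`, "", 2L))
}

#' Specify a ChIP/input simulation
#'
#' @param enrichment named numeric vector of multiplicative enrichment
#'   factors (>= 0), names a subset of the planted family names; factor 1
#'   means sampling proportional to the genomic fraction. The regime of
#'   interest for centromeric satellites is roughly 40- to 150-fold.
#' @param n_chip,n_input read counts for the two pools (>= 0)
#' @param read_length read length (default 101)
#' @param error_rate per-base substitution error probability
#' @param qualities a [quality_model()]
#' @param seed integer seed
#' @return an object of class `chip_sim_spec`
#' @export
chip_sim_spec <- function(enrichment, n_chip, n_input, read_length = 101L,
                          error_rate = 0, qualities = quality_model(),
                          seed = 1L) {
  stopifnot(is.numeric(enrichment), !is.null(names(enrichment)))
  if (any(enrichment < 0))
    stop("enrichment factors must be >= 0", call. = FALSE)
  n_chip <- .stopifnot_scalar_int(n_chip, "n_chip", 0L)
  n_input <- .stopifnot_scalar_int(n_input, "n_input", 0L)
  structure(list(enrichment = enrichment, n_chip = n_chip, n_input = n_input,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, qualities = qualities,
                 seed = as.integer(seed)),
            class = "chip_sim_spec")
}

# complement of the array intervals within [0, L) as a data.frame(start, end)
.background_intervals <- function(truth) {
  a <- truth$arrays[order(truth$arrays$start), , drop = FALSE]
  bounds <- c(0L, rbind(a$start, a$end), truth$genome_length)
  s <- bounds[seq(1L, length(bounds), by = 2L)]
  e <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# sample n uniform 1-based start positions within a set of 0-based half-open
# intervals, clamped so reads of length rl stay inside [0, L)
.sample_starts <- function(iv, n, rl, L) {
  if (n == 0L) return(integer(0))
  len <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = len)
  off <- floor(runif(n) * len[pick])
  pmin(iv$start[pick] + off + 1L, L - rl + 1L)
}

#' Simulate ChIP and input read pools with planted enrichment
#'
#' Input reads sample each planted family proportionally to its genomic
#' fraction; ChIP reads sample it with probability fraction x enrichment
#' factor, the immunoprecipitation depleting the unbound background bulk
#' (whose sampling weight is whatever remains). A factor of 1 therefore means
#' sampling exactly proportional to the genomic fraction in both pools, and
#' the expected ChIP/input proportion ratio of a family equals its planted
#' factor. The summed fraction x factor mass must stay below 1. Within a
#' family, start positions are uniform over its array; background reads are
#' uniform over the non-array remainder. Reads are labeled by the category
#' they were sampled from (read names `c000001:start:strand:family`).
#'
#' @param truth a `synthetic_truth` from [build_genome()]
#' @param spec a [chip_sim_spec()]
#' @param genome the matching genome `DNAStringSet`
#' @return list with `chip` and `input`, each a `QualityScaledDNAStringSet`
#' @export
simulate_chip <- function(truth, spec, genome) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(spec, "chip_sim_spec"))
  fams <- truth$arrays$family
  unknown <- setdiff(names(spec$enrichment), fams)
  if (length(unknown))
    stop("enrichment factors for unknown families: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  fac <- setNames(rep(1, length(fams)), fams)
  fac[names(spec$enrichment)] <- spec$enrichment
  frac <- truth_fractions(truth)[fams]
  bg_frac <- 1 - sum(frac)
  g <- if (is(genome, "DNAStringSet")) genome[[1L]] else .as_dna(genome)
  gchr <- as.character(g)
  L <- length(g)
  rl <- spec$read_length
  bg_iv <- .background_intervals(truth)
  fam_iv <- lapply(seq_along(fams), function(i)
    truth$arrays[i, c("start", "end"), drop = FALSE])

  sample_pool <- function(n, weights, prefix) {
    w <- weights / sum(weights)
    cat_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    starts1 <- integer(n)
    for (i in seq_along(fams)) {
      hit <- cat_idx == i
      if (any(hit)) starts1[hit] <- .sample_starts(fam_iv[[i]], sum(hit), rl, L)
    }
    hit <- cat_idx == length(w)
    if (any(hit)) starts1[hit] <- .sample_starts(bg_iv, sum(hit), rl, L)
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- .reads_from_positions(gchr, starts1, strand, rl, spec$error_rate)
    quals <- .make_quals(n, rl, spec$qualities)
    labels <- c(fams, "background")[cat_idx]
    ids <- sprintf("%s%06d:%d:%s:%s", prefix, seq_len(n), starts1 - 1L,
                   strand, labels)
    .make_qreads(seqs, quals, ids)
  }

  chip_mass <- sum(frac * fac)
  if (chip_mass >= 1)
    stop("planted fraction x enrichment mass reaches ", round(chip_mass, 3),
         "; must be < 1", call. = FALSE)
  withr::with_seed(spec$seed, {
    chip_w <- c(frac * fac, background = 1 - chip_mass)
    input_w <- c(frac, background = bg_frac)
    chip <- sample_pool(spec$n_chip, chip_w, "c")
    input <- sample_pool(spec$n_input, input_w, "i")
    list(chip = chip, input = input)
  })
}

#' True sampling category of simulated ChIP/input reads
#'
#' @param reads reads from [simulate_chip()]
#' @return character vector of family names (or `"background"`)
#' @export
true_family <- function(reads) {
  vapply(strsplit(names(reads), ":", fixed = TRUE), `[[`, "", 4L)
}
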