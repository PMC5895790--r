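#' Physical size from genome percentage
#'
#' Converts a genomic abundance percentage into Mbp per 1C (haploid genome),
#' reported at one decimal (half-away-from-zero).
#'
#' @param pct genomic abundance in percent (>= 0)
#' @param genome_mbp haploid (1C) genome size in Mbp; default 13410 (a
#'   13.41 Gbp genome)
#' @return Mbp/1C, one decimal
#' @examples
#' mbp_per_1c(2.322)  # 311.4
#' @export
mbp_per_1c <- function(pct, genome_mbp = 13410) {
  if (any(pct < 0)) stop("`pct` must be >= 0", call. = FALSE)
  stopifnot(genome_mbp > 0)
  round_half_away(pct / 100 * genome_mbp, 1)
}

#' Read the packaged satellite summary table
#'
#' The package ships a 26-family summary fixture (23 novel `VfSat` families
#' plus three previously described repeats) transcribed losslessly: an
#' approximate monomer length carries `monomer_approx = TRUE`, and a length
#' variant (e.g. a 59/57 bp doublet) is kept in `monomer_bp_variant`.
#'
#' @param path TSV path; defaults to the packaged fixture
#' @return data.frame with one row per satellite family (columns: satellite,
#'   monomer_bp, monomer_bp_variant, monomer_approx, pct_genome, mbp_1c,
#'   pct_at, max_at, max_cg, max_pupy, chip_input_ratio, centromere, notes)
#' @export
read_satellite_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_satellites.tsv", package = "satkit",
                        mustWork = TRUE)
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed satellite table `", path, "`: ",
                             conditionMessage(e), call. = FALSE))
  for (col in intersect(c("satellite", "centromere", "notes"), names(df)))
    df[[col]] <- as.character(df[[col]])
  required <- c("satellite", "monomer_bp", "pct_genome", "mbp_1c", "pct_at",
                "max_at", "max_cg", "max_pupy", "chip_input_ratio")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("satellite table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!complete.cases(df[setdiff(required, "satellite")]))
  if (length(bad))
    stop("malformed satellite table row(s): line ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  df
}

#' Write a satellite summary table
#'
#' Fixed column order; `read_satellite_table(write_satellite_table(x, p))`
#' returns `x` unchanged.
#'
#' @param records data.frame as returned by [read_satellite_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_satellite_table <- function(records, path) {
  cols <- c("satellite", "monomer_bp", "monomer_bp_variant", "monomer_approx",
            "pct_genome", "mbp_1c", "pct_at", "max_at", "max_cg", "max_pupy",
            "chip_input_ratio", "centromere", "notes")
  cols <- c(intersect(cols, names(records)),
            setdiff(names(records), cols))
  write.table(records[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Count satellite families satisfying a predicate
#'
#' @param table satellite summary data.frame
#' @param predicate one-sided formula evaluated in the table's columns, e.g.
#'   `~ pct_genome > 0.1` or `~ startsWith(satellite, "VfSat")`; referencing
#'   an unknown column is an error
#' @return integer count
#' @examples
#' tab <- read_satellite_table()
#' fixture_counts(tab, ~ pct_genome > 0.1)
#' @export
fixture_counts <- function(table, predicate) {
  stopifnot(is.data.frame(table), nrow(table) > 0, inherits(predicate, "formula"))
  expr <- predicate[[length(predicate)]]
  vars <- all.vars(expr)
  known_funs <- vars %in% c(ls(baseenv()), "TRUE", "FALSE")
  unknown <- setdiff(vars[!known_funs], names(table))
  if (length(unknown))
    stop("unknown field(s) in predicate: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  res <- eval(expr, envir = table, enclos = baseenv())
  if (!is.logical(res))
    stop("predicate must evaluate to a logical vector", call. = FALSE)
  sum(res, na.rm = TRUE)
}

#' Audit printed physical sizes against recomputation
#'
#' Recomputes Mbp/1C from each row's genome percentage and reports every row
#' whose recomputed one-decimal value disagrees with the printed one.
#' Discrepancies (typically rounding of the percentage itself) are reported,
#' never silently corrected.
#'
#' @param table satellite summary data.frame
#' @param genome_mbp 1C genome size in Mbp
#' @return data.frame of discrepant rows: satellite, pct_genome, mbp_printed,
#'   mbp_recomputed
#' @export
audit_physical_size <- function(table, genome_mbp = 13410) {
  recomputed <- mbp_per_1c(table$pct_genome, genome_mbp)
  bad <- abs(recomputed - table$mbp_1c) > 0.05
  data.frame(satellite = table$satellite[bad],
             pct_genome = table$pct_genome[bad],
             mbp_printed = table$mbp_1c[bad],
             mbp_recomputed = recomputed[bad],
             stringsAsFactors = FALSE)
}

#' Read the replication-timing class table
#'
#' Three ordinal S-phase classes: `mid` (centromeric repeats and one
#' early-replicating family), `late` (most satellites), `latest` (the single
#' family replicating last).
#'
#' @param path TSV path; defaults to the packaged fixture
#' @return data.frame with columns `satellite` and `timing_class` (factor
#'   with ordered levels mid < late < latest)
#' @export
read_replication_timing <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "replication_timing.tsv",
                        package = "satkit", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$timing_class), c("mid", "late", "latest"))
  if (length(bad))
    stop("unknown timing class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$timing_class <- factor(df$timing_class, levels = c("mid", "late", "latest"),
                            ordered = TRUE)
  df
}

#' Regress replication timing on sequence features
#'
#' Tests whether sequence composition predicts replication timing. Timing is
#' encoded ordinally (mid = 0, late = 1, latest = 2, preserving the S-phase
#' order) and regressed on each feature singly by ordinary least squares with
#' a two-sided slope test. No multiple-testing correction is applied by
#' default.
#'
#' @param features data.frame of numeric per-family features (rows matched to
#'   `timing` by position, or by a `satellite` column present in both)
#' @param timing a factor/character of classes `mid`/`late`/`latest`, or a
#'   data.frame as from [read_replication_timing()]
#' @param adjust p-value adjustment: `"none"` (default) or `"BH"`
#' @return data.frame: feature, slope, statistic, p_value (and `p_adjusted`
#'   when `adjust != "none"`); a constant feature yields `NA` with a warning
#' @export
replication_regression <- function(features, timing, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(timing)) {
    if ("satellite" %in% names(features) && "satellite" %in% names(timing))
      timing <- timing$timing_class[match(features$satellite,
                                          timing$satellite)]
    else timing <- timing$timing_class
  }
  y <- c(mid = 0, late = 1, latest = 2)[as.character(timing)]
  if (anyNA(y)) stop("timing classes must be mid/late/latest", call. = FALSE)
  num <- vapply(features, is.numeric, TRUE)
  features <- features[num]
  if (ncol(features) == 0L) stop("no numeric features", call. = FALSE)
  if (length(y) < ncol(features) + 2L && length(y) < 3L)
    stop("too few families for regression", call. = FALSE)
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("feature `", f, "` is constant; returning NA", call. = FALSE)
      return(data.frame(feature = f, slope = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- summary(lm(y ~ x))$coefficients
    data.frame(feature = f, slope = fit["x", "Estimate"],
               statistic = fit["x", "t value"],
               p_value = fit["x", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust != "none") out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out
}
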