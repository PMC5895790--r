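#!/usr/bin/env Rscript

# Tandem-organization validation on the synthetic arrays: period estimation,
# dot-plot subrepeat screening, outward-facing primer design, in-silico PCR
# across array junctions, and clone-vs-consensus identity.

suppressPackageStartupMessages(library(satkit))
stopifnot(file.exists("results/genome.fa"))  # run 02_simulate.R first
seed <- 1L

mono <- read_fasta("results/monomers.fa")
truth <- read.delim("results/truth.tsv")
genome <- as.character(read_fasta("results/genome.fa")[[1]])

rows <- lapply(seq_len(nrow(truth)), function(i) {
  arr <- substr(genome, truth$start[i] + 1, truth$end[i])
  est <- estimate_period(arr, min_period = 2)
  sub <- detect_subrepeats(as.character(mono[[truth$family[i]]]),
                           min_len = 15)
  # primer length adapts to the monomer: outward geometry needs 2L+1 bases
  max_len <- min(25L, (truth$monomer_length[i] - 1L) %/% 2L)
  pair <- withCallingHandlers(
    design_outward_primers(as.character(mono[[truth$family[i]]]),
                           lengths = 15:max_len, gc_range = c(0.3, 0.7)),
    warning = function(w) invokeRestart("muffleWarning"))
  prods <- in_silico_pcr(arr, pair)
  clone_span <- substr(arr, 1, min(nchar(arr), 3 * truth$monomer_length[i]))
  pid <- percent_identity(
    clone_span, strrep(as.character(mono[[truth$family[i]]]), 3))
  data.frame(family = truth$family[i],
             monomer_bp = truth$monomer_length[i],
             period_estimate = est$period,
             period_confidence = round(est$confidence, 3),
             subrepeats = nrow(sub),
             n_copies = truth$n_copies[i],
             pcr_products = length(prods),
             pcr_product_bp = if (length(prods)) prods[1] else NA,
             clone_identity_pct = round(pid, 1))
})
val <- do.call(rbind, rows)
cat("tandem validation (period estimates vs planted monomer lengths,\n")
cat("junction products vs copy number, clone identity vs 5% divergence).\n")
cat("On clean arrays an outward pair gives exactly n-1 junction products;\n")
cat("here 5% copy divergence breaks exact primer sites in part of the\n")
cat("copies, so products appear at a subset of junctions - still possible\n")
cat("only because monomers are tandemly arranged:\n")
print(val, row.names = FALSE)
write.table(val, "results/monomer_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/monomer_validation.tsv\n")
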