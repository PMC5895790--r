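#!/usr/bin/env Rscript

# Sequence-composition statistics: AT content, strand-asymmetry indices and
# Karlin-style di-/tri-nucleotide relative abundances for the planted
# monomers, plus the read-pool variant on oriented shotgun reads.

suppressPackageStartupMessages(library(satkit))
stopifnot(file.exists("results/monomers.fa"))  # run 02_simulate.R first

mono <- read_fasta("results/monomers.fa")
rows <- lapply(names(mono), function(f) {
  p <- composition_profile(mono[[f]])
  data.frame(name = f, length = length(mono[[f]]),
             pct_at = round(100 * p$at_fraction, 1),
             max_at = round(p$max_at, 2), max_cg = round(p$max_cg, 2),
             max_pupy = round(p$max_pupy, 2),
             t(round(p$rho, 3)), t(round(p$gamma, 3)),
             check.names = FALSE)
})
prof <- do.call(rbind, rows)
cat("monomer composition profiles:\n")
print(prof[1:6], row.names = FALSE)
write.table(prof, "results/composition_monomers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# the VfSat2-style simple-sequence motif: short AT-rich unit with strong
# strand asymmetry, the behavior expected of a degenerated (GTT)n repeat
motif <- paste0("TATTTGAC", strrep("GTT", 6))
pm <- composition_profile(motif)
cat(sprintf("\nTATTTGAC(GTT)6 motif: %d bp, %.1f%% AT, max A/T %.2f, max Pu/Py %.2f\n",
            nchar(motif), 100 * pm$at_fraction, pm$max_at, pm$max_pupy))

# unassembled-read variant: pooled counts after orienting reads to the
# consensus strand
reads <- process_fastq("results/shotgun.fastq", qc_params())$reads
fam <- "satA"
asn <- assign_reads(reads, reference_set(mono))
sel <- reads[!is.na(asn$assignments$family) &
             asn$assignments$family[match(names(reads),
                                          asn$assignments$read_id)] == fam]
pp <- pool_composition(sel, mono[[fam]])
cat(sprintf("\n%s from %d assigned reads: %.1f%% AT (monomer: %.1f%%)\n",
            fam, length(sel), 100 * pp$at_fraction,
            100 * at_content(mono[[fam]])))
pool_row <- data.frame(name = paste0(fam, "_readpool"), length = NA,
                       pct_at = round(100 * pp$at_fraction, 1),
                       max_at = round(pp$max_at, 2),
                       max_cg = round(pp$max_cg, 2),
                       max_pupy = round(pp$max_pupy, 2),
                       t(round(pp$rho, 3)), t(round(pp$gamma, 3)),
                       check.names = FALSE)
write.table(pool_row, "results/composition_readpool.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/composition_{monomers,readpool}.tsv\n")
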