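#!/usr/bin/env Rscript

# Read QC, best-hit assignment and the abundance / enrichment tables on the
# simulated pools from 02_simulate.R, scored against the planted truth.

suppressPackageStartupMessages(library(satkit))
stopifnot(file.exists("results/shotgun.fastq"))  # run 02_simulate.R first
seed <- 1L

truth <- read.delim("results/truth.tsv")
refs <- reference_set(truth_references(structure(list(
  arrays = truth[c("family", "start", "end", "monomer_length", "n_copies")],
  fractions = setNames(truth$fraction, truth$family),
  monomers = read_fasta("results/monomers.fa"),
  genome_length = 200000L), class = "synthetic_truth")))

qc <- process_fastq("results/shotgun.fastq", qc_params())
cat("shotgun QC:\n"); print(qc$summary)

asn <- assign_reads(qc$reads, refs)
ab <- abundance_table(asn, genome_size_mbp = 13410)
ab$planted_fraction_pct <- truth$fraction[match(ab$family, truth$family)] * 100
cat("\nabundance vs planted fractions:\n")
print(ab, row.names = FALSE)
write.table(ab, "results/abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

chip <- process_fastq("results/chip.fastq", qc_params())$reads
input <- process_fastq("results/input.fastq", qc_params())$reads
et <- enrichment_table(assign_reads(chip, refs), assign_reads(input, refs),
                       enrichment_params(denominator = "all"))
et$planted_factor <- truth$enrichment[match(et$family, truth$family)]
cat("\nChIP/input enrichment vs planted factors:\n")
print(et[c("family", "chip_count", "input_count", "ratio",
           "planted_factor", "call")], row.names = FALSE)
write.table(et, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nmulti-seed recovery study (factors 1/10/100, 10 seeds):\n")
rec <- enrichment_recovery_study(seeds = seed + 0:9)
med <- tapply(rec$rel_error, rec$planted, median)
print(round(med, 4))
write.table(rec, "results/enrichment_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/{abundance,enrichment,enrichment_recovery}.tsv\n")
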