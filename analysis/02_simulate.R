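#!/usr/bin/env Rscript

# Builds the synthetic study genome: three satellite families spanning the
# short/typical monomer range with planted genomic fractions, plus shotgun
# and ChIP/input read pools with known enrichment factors. Everything
# downstream is scored against this planted truth.

suppressPackageStartupMessages(library(satkit))
dir.create("results", showWarnings = FALSE)
seed <- 1L

fams <- list(satellite_family("satA", 191, 0.75, 0.05, 0.02),
             satellite_family("satB", 58, 0.55, 0.05, 0.01),
             satellite_family("satC", 50, 0.65, 0.05, 0.004))
g <- build_genome(genome_spec(200000, fams, seed = seed))
cat("genome:", Biostrings::width(g$genome), "bp; planted fractions:\n")
print(round(truth_fractions(g$truth), 5))

write_fasta(g$genome, "results/genome.fa")
write_fasta(g$truth$monomers, "results/monomers.fa")
write_truth(g$truth, "results/truth.tsv",
            enrichment = c(satA = 1, satB = 10, satC = 100))

shotgun <- simulate_reads(g$genome, 50000, 101, error_rate = 0.01,
                          seed = seed + 1)
write_fastq(shotgun, "results/shotgun.fastq")

spec <- chip_sim_spec(c(satA = 1, satB = 10, satC = 100),
                      n_chip = 100000, n_input = 100000,
                      error_rate = 0.01, seed = seed + 2)
pools <- simulate_chip(g$truth, spec, g$genome)
write_fastq(pools$chip, "results/chip.fastq")
write_fastq(pools$input, "results/input.fastq")
cat("wrote results/{genome,monomers}.fa and results/{shotgun,chip,input}.fastq\n")
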