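test_that("make_monomer respects length, alphabet and AT target", {
  m <- make_monomer(4, 1.0, seed = 3)
  expect_equal(length(m), 4L)
  expect_true(grepl("^[AT]+$", as.character(m)))

  m2 <- make_monomer(1000, 0.75, seed = 1)
  at <- at_content(m2)
  expect_lt(abs(at - 0.75), 0.05)

  expect_error(make_monomer(0, 0.5, 1), "length")
  expect_identical(as.character(make_monomer(50, 0.6, seed = 9)),
                   as.character(make_monomer(50, 0.6, seed = 9)))
  expect_false(identical(as.character(make_monomer(50, 0.6, seed = 9)),
                         as.character(make_monomer(50, 0.6, seed = 10))))
})

test_that("build_genome plants arrays at the requested fractions", {
  # degenerate case: one family fills the genome exactly
  fam <- satellite_family("satA", 100, 0.7, divergence = 0,
                          target_fraction = 1)
  g <- build_genome(genome_spec(1000, list(fam), seed = 1))
  expect_equal(Biostrings::width(g$genome), 1000L)
  expect_equal(unname(truth_fractions(g$truth)), 1)
  expect_equal(g$truth$arrays$n_copies, 10L)
  # the array is 10 identical copies of the consensus
  expect_identical(as.character(g$genome[[1]]),
                   strrep(as.character(g$truth$monomers[[1]]), 10))

  # fraction honored to within one monomer
  fam2 <- satellite_family("satB", 191, 0.75, 0.05, target_fraction = 0.10)
  g2 <- build_genome(genome_spec(100000, list(fam2), seed = 2))
  expect_lte(abs(truth_fractions(g2$truth) - 0.10), 191 / 100000)

  # two families: disjoint arrays, fractions consistent
  fams <- list(satellite_family("a", 50, 0.7, 0.02, 0.2),
               satellite_family("b", 80, 0.6, 0.02, 0.3))
  g3 <- build_genome(genome_spec(50000, fams, seed = 3))
  arr <- g3$truth$arrays
  expect_true(all(arr$end[-nrow(arr)] <= arr$start[-1]))
  expect_lte(sum(truth_fractions(g3$truth)), 1)
  expect_equal(truth_fractions(g3$truth),
               g3$truth$fractions)

  expect_error(build_genome(genome_spec(500, list(
    satellite_family("x", 300, 0.5, 0, 1)))), "infeasible")
})

test_that("genome construction is deterministic under a fixed seed", {
  spec <- genome_spec(20000, list(satellite_family("s", 37, 0.65, 0.05, 0.15)),
                      seed = 42)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$arrays, g2$truth$arrays)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulate_reads samples uniformly from both strands without errors", {
  g <- build_genome(genome_spec(100000,
    list(satellite_family("s", 191, 0.75, 0.05, 0.10)), seed = 5))
  gc <- as.character(g$genome[[1]])

  rd <- simulate_reads(g$genome, 20, 101, error_rate = 0, seed = 6)
  expect_equal(length(rd), 20L)
  for (i in seq_len(20)) {
    fwd <- as.character(rd[[i]])
    rev <- revcomp_chr(fwd)
    expect_true(grepl(fwd, gc, fixed = TRUE) || grepl(rev, gc, fixed = TRUE))
  }

  expect_equal(length(simulate_reads(g$genome, 0, 101, 0, seed = 1)), 0L)
  expect_error(simulate_reads(g$genome, -1, 101, 0, 1), "n_reads")
  expect_error(simulate_reads(Biostrings::DNAString("ACGT"), 5, 101, 0, 1),
               "read_length")

  # start positions hit the planted array at its genomic fraction
  rd2 <- simulate_reads(g$genome, 50000, 101, 0, seed = 7)
  p <- unname(truth_fractions(g$truth))
  st <- read_start_positions(rd2)
  arr <- g$truth$arrays
  inside <- mean(st >= arr$start & st < arr$end)
  tol <- 3 * sqrt(p * (1 - p) / 50000)
  expect_lt(abs(inside - p), tol + 101 / 100000)  # edge slack: start window

  # byte-identical FASTQ under a fixed seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g$genome, 100, 101, 0.01, seed = 8), f1)
  write_fastq(simulate_reads(g$genome, 100, 101, 0.01, seed = 8), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulate_chip plants the requested pool composition", {
  g <- build_genome(genome_spec(50000,
    list(satellite_family("a", 100, 0.7, 0.02, 0.05),
         satellite_family("b", 60, 0.6, 0.02, 0.02)), seed = 9))
  spec <- chip_sim_spec(c(a = 1, b = 20), n_chip = 20000, n_input = 20000,
                        seed = 10)
  pools <- simulate_chip(g$truth, spec, g$genome)
  expect_equal(length(pools$chip), 20000L)
  expect_equal(length(pools$input), 20000L)

  # labels agree with start coordinates for array-derived reads
  lab <- true_family(pools$input)
  st <- read_start_positions(pools$input)
  arr <- g$truth$arrays
  for (i in seq_len(nrow(arr))) {
    hit <- lab == arr$family[i]
    expect_true(all(st[hit] >= arr$start[i] & st[hit] < arr$end[i]))
  }

  # input pool samples each family at its genomic fraction (3 binomial sd)
  frac <- truth_fractions(g$truth)
  for (f in names(frac)) {
    obs <- mean(lab == f)
    expect_lt(abs(obs - frac[[f]]),
              3 * sqrt(frac[[f]] * (1 - frac[[f]]) / 20000))
  }
  # chip pool samples family b at fraction x factor
  labc <- true_family(pools$chip)
  pb <- frac[["b"]] * 20
  expect_lt(abs(mean(labc == "b") - pb), 3 * sqrt(pb * (1 - pb) / 20000))
  # factor-1 family unchanged in the chip pool
  pa <- frac[["a"]]
  expect_lt(abs(mean(labc == "a") - pa), 3 * sqrt(pa * (1 - pa) / 20000))

  # degenerate and invalid cases
  empty <- simulate_chip(g$truth,
    chip_sim_spec(c(a = 1), n_chip = 0, n_input = 50, seed = 1), g$genome)
  expect_equal(length(empty$chip), 0L)
  expect_equal(length(empty$input), 50L)
  expect_error(chip_sim_spec(c(a = -1), 10, 10), ">= 0")
  expect_error(simulate_chip(g$truth,
    chip_sim_spec(c(zz = 1), 10, 10), g$genome), "unknown")
})

test_that("truth references multimerize short monomers to mappable length", {
  g <- build_genome(genome_spec(20000,
    list(satellite_family("short", 50, 0.6, 0, 0.05),
         satellite_family("long", 963, 0.7, 0, 0.10)), seed = 4))
  refs <- truth_references(g$truth, min_length = 202)
  expect_gte(min(Biostrings::width(refs)), 202)
  expect_identical(as.character(refs[["long"]]),
                   as.character(g$truth$monomers[["long"]]))
  expect_identical(as.character(refs[["short"]]),
                   strrep(as.character(g$truth$monomers[["short"]]), 5))
})
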