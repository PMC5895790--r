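test_that("local alignment scores match hand-derived values", {
  set.seed(21)
  a <- random_dna(100)
  expect_equal(local_align_score(a, a), 200L)

  b <- a
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 50, 50))[1]
  expect_equal(local_align_score(b, a), 195L)  # 99 x 2 - 3

  expect_equal(local_align_score(strrep("AT", 30), strrep("GC", 30)), 0L)
  expect_error(local_align_score("", "ACGT"), "non-empty")
})

test_that("scores agree exactly with a brute-force affine DP oracle", {
  set.seed(22)
  for (i in 1:200) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    expect_identical(local_align_score(a, b), as.integer(sw_oracle(a, b)),
                     info = paste(a, b))
  }
})

test_that("scores agree with Biostrings local alignment on gapped instances", {
  # independent cross-check on longer sequences where gaps pay off
  set.seed(23)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    a <- random_dna(120)
    # embed a with an internal deletion into random flanks
    core <- paste0(substr(a, 1, 60), substr(a, 66, 120))
    b <- paste0(random_dna(30), core, random_dna(30))
    ours <- local_align_score(a, b)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2))
    expect_equal(ours, as.integer(ref))
  }
})

test_that("reads are assigned to the best family with deterministic ties", {
  g <- build_genome(genome_spec(30000,
    list(satellite_family("famA", 150, 0.7, 0, 0.2),
         satellite_family("famB", 150, 0.4, 0, 0.2)), seed = 24))
  refs <- reference_set(g$truth$monomers)
  rd <- simulate_reads(g$genome, 500, 101, 0, seed = 25)
  asn <- assign_reads(rd, refs)
  lab <- ifelse(read_start_positions(rd) >= g$truth$arrays$start[1] &
                read_start_positions(rd) < g$truth$arrays$end[1] - 101,
                "famA", NA)
  # every read fully inside famA's array is assigned to famA
  expect_true(all(asn$assignments$family[order(names(rd))][
    !is.na(lab[order(names(rd))])] == "famA"))

  # tie between two identical references goes to the smaller name
  tied <- reference_set(c(zeta = strrep("ACGGTTA", 30),
                          alpha = strrep("ACGGTTA", 30)))
  read <- substr(strrep("ACGGTTA", 30), 10, 110)
  asn2 <- assign_reads(c(x = read), tied)
  expect_identical(asn2$assignments$family, "alpha")
  expect_equal(asn2$ties, 1L)

  # random reads score below a permissive threshold against unrelated refs
  set.seed(26)
  rand <- vapply(1:50, function(i) random_dna(100), "")
  asn3 <- assign_reads(rand, reference_set(c(u = random_dna(500))),
                       align_params(min_score = 40L, word_size = 0L))
  expect_equal(asn3$unassigned, 50L)
})

test_that("word-size seeding does not change assignments", {
  # moderately diverged, error-free reads: every assignable read retains an
  # exact 9-mer, so the seed filter is a pure accelerator here
  g <- build_genome(genome_spec(40000,
    list(satellite_family("fam", 191, 0.75, 0.03, 0.15)), seed = 27))
  rd <- simulate_reads(g$genome, 400, 101, 0, seed = 28)
  refs <- reference_set(truth_references(g$truth))
  seeded <- assign_reads(rd, refs, align_params(word_size = 9L))
  full <- assign_reads(rd, refs, align_params(word_size = 0L))
  expect_identical(seeded$assignments, full$assignments)
})

test_that("assignment output is invariant to read order", {
  g <- build_genome(genome_spec(20000,
    list(satellite_family("fam", 100, 0.7, 0.02, 0.2)), seed = 29))
  rd <- simulate_reads(g$genome, 200, 101, 0, seed = 30)
  refs <- reference_set(truth_references(g$truth))
  a1 <- assign_reads(rd, refs)
  set.seed(31)
  a2 <- assign_reads(rd[sample(length(rd))], refs)
  expect_identical(a1$assignments, a2$assignments)
  expect_identical(a1$counts, a2$counts)
})

test_that("abundance table reproduces the percentage and Mbp arithmetic", {
  asn <- fake_assignment(c(fok = 2322L), total = 100000L)
  tab <- abundance_table(asn, 13410)
  expect_equal(tab$pct_genome, 2.322)
  expect_equal(tab$mbp_1c, 311.4)

  asn2 <- fake_assignment(c(a = 0L, b = 250L), total = 1000L)
  tab2 <- abundance_table(asn2, 13410)
  expect_equal(tab2$pct_genome[tab2$family == "a"], 0)
  expect_equal(tab2$mbp_1c[tab2$family == "a"], 0)
  # fractions plus unassigned account for every read
  expect_equal(sum(tab2$pct_genome) + asn2$unassigned / asn2$total * 100, 100)

  expect_error(abundance_table(fake_assignment(c(a = 0L), total = 0L), 13410),
               "reads")
})

test_that("enrichment ratios, floors and the strict threshold behave", {
  # identity case: equal proportions, no calls
  chip <- fake_assignment(c(a = 500L, b = 100L), total = 10000L)
  input <- fake_assignment(c(a = 500L, b = 100L), total = 10000L)
  et <- enrichment_table(chip, input, enrichment_params())
  expect_equal(et$ratio, c(1, 1))
  expect_false(any(et$call))

  # ratio exactly 10 is NOT called (strict inequality)
  chip10 <- fake_assignment(c(a = 1000L, b = 1000L), total = 10000L)
  inp10 <- fake_assignment(c(a = 100L, b = 1900L), total = 10000L)
  et10 <- enrichment_table(chip10, inp10,
                           enrichment_params(denominator = "all"))
  expect_equal(et10$ratio[et10$family == "a"], 10)
  expect_false(et10$call[et10$family == "a"])

  # zero input with nonzero chip: infinity sentinel, floor from the chip pool
  chipi <- fake_assignment(c(a = 1000L, b = 1000L), total = 10000L)
  inpi <- fake_assignment(c(a = 0L, b = 2000L), total = 10000L)
  eti <- enrichment_table(chipi, inpi, enrichment_params(denominator = "all"))
  expect_identical(eti$ratio[eti$family == "a"], Inf)
  expect_true(eti$call[eti$family == "a"])

  # families below the genomic-proportion floor are never evaluated
  chipf <- fake_assignment(c(a = 50L, b = 5000L), total = 1e6L)
  inpf <- fake_assignment(c(a = 1L, b = 5000L), total = 1e6L)
  etf <- enrichment_table(chipf, inpf, enrichment_params(denominator = "all"))
  expect_false(etf$evaluated[etf$family == "a"])  # 1e-4 % < 0.002 %
  expect_false(etf$call[etf$family == "a"])
})

test_that("swapping chip and input pools inverts every finite ratio", {
  set.seed(32)
  for (i in 1:5) {
    c1 <- fake_assignment(setNames(as.integer(sample(1:500, 4)), letters[1:4]),
                          total = 5000L)
    c2 <- fake_assignment(setNames(as.integer(sample(1:500, 4)), letters[1:4]),
                          total = 5000L)
    fwd <- enrichment_table(c1, c2, enrichment_params())
    rev <- enrichment_table(c2, c1, enrichment_params())
    expect_equal(fwd$ratio, 1 / rev$ratio, tolerance = 1e-12)
  }
})

test_that("pool proportions are normalized", {
  chip <- fake_assignment(c(a = 123L, b = 456L, c = 1L), total = 1000L)
  input <- fake_assignment(c(a = 50L, b = 60L, c = 70L), total = 1000L)
  et <- enrichment_table(chip, input, enrichment_params())
  expect_lt(abs(sum(et$chip_proportion) - 1), 1e-12)
  expect_lt(abs(sum(et$input_proportion) - 1), 1e-12)
  eta <- enrichment_table(chip, input, enrichment_params(denominator = "all"))
  expect_lt(abs(sum(eta$chip_proportion) + chip$unassigned / chip$total - 1),
            1e-12)
})
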