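test_that("period estimation recovers clean and diverged tandem periods", {
  est <- estimate_period(strrep("ACGTT", 20))
  expect_equal(est$period, 5L)
  expect_equal(est$confidence, 1)

  expect_equal(estimate_period(strrep("A", 50))$period, 1L)

  # 5% per-copy divergence, 191-bp monomer, 50 copies
  g <- build_genome(genome_spec(191 * 50,
    list(satellite_family("m", 191, 0.75, 0.05, 1)), seed = 51))
  est2 <- estimate_period(as.character(g$genome[[1]]), min_period = 2)
  expect_equal(est2$period, 191L)
  expect_gt(est2$confidence, 0.85)

  expect_error(estimate_period("ACGT", min_period = 10), "short")
})

test_that("period estimation is minimal and rotation-invariant", {
  set.seed(52)
  for (i in 1:5) {
    mono <- random_dna(sample(20:60, 1))
    arr <- strrep(mono, 30)
    expect_equal(estimate_period(arr)$period, nchar(mono))
    rot <- sample(nchar(arr) - 1, 1)
    rotated <- paste0(substr(arr, rot + 1, nchar(arr)), substr(arr, 1, rot))
    expect_equal(estimate_period(rotated)$period, nchar(mono))
  }
})

test_that("dot-plot subrepeat detection flags only real internal structure", {
  set.seed(53)
  expect_equal(nrow(detect_subrepeats(random_dna(1000), min_len = 20)), 0L)

  half <- random_dna(500)
  doubled <- paste0(half, half)
  sub <- detect_subrepeats(doubled, min_len = 20)
  expect_true(500 %in% sub$period)
  expect_equal(max(sub$length[sub$period == 500]), 500L)

  expect_error(detect_subrepeats(random_dna(30), min_len = 20), "min_len")
})

test_that("outward primer design satisfies geometry and composition rules", {
  set.seed(54)
  mono <- random_dna(1000)  # ~50% GC
  pair <- design_outward_primers(mono)
  expect_s3_class(pair, "primer_pair")
  expect_lte(pair$reverse$end, pair$forward$start)
  expect_true(nchar(pair$forward$seq) %in% 18:25)
  expect_true(nchar(pair$reverse$seq) %in% 18:25)
  expect_false(pair$relaxed)
  # forward primer is the monomer site itself; reverse is its complement
  expect_identical(pair$forward$seq,
                   substr(mono, pair$forward$start + 1, pair$forward$end))
  expect_identical(pair$reverse$seq,
                   revcomp_chr(substr(mono, pair$reverse$start + 1,
                                      pair$reverse$end)))

  expect_error(design_outward_primers(random_dna(30)), "too short")

  # AT-rich monomer where every candidate site has 33% GC: the preferred
  # 40-60% window is unattainable, the relaxed floor is not
  at_rich <- strrep("TAG", 200)
  expect_warning(pair2 <- design_outward_primers(at_rich), "relax")
  expect_true(pair2$relaxed)
  expect_lte(pair2$reverse$end, pair2$forward$start)

  # no G/C at all: even the relaxed floor fails
  at_only <- random_dna(600, bases = c("A", "T"))
  expect_error(suppressWarnings(design_outward_primers(at_only)),
               "no valid primer")
})

test_that("in-silico PCR amplifies only across tandem junctions", {
  set.seed(55)
  mono <- random_dna(1000)
  pair <- design_outward_primers(mono)

  # single monomer: outward primers cannot produce a product
  expect_length(in_silico_pcr(mono, pair), 0)

  # n copies -> exactly n-1 equal junction products
  L <- nchar(mono)
  expected <- (L - pair$forward$start) + pair$reverse$end
  for (n in c(2, 3, 10)) {
    prods <- in_silico_pcr(strrep(mono, n), pair)
    expect_equal(length(prods), n - 1)
    expect_true(all(prods == expected))
  }

  # constructed junction arithmetic: forward site [900,920), reverse [130,150)
  pair_manual <- list(forward = substr(mono, 901, 920),
                      reverse = revcomp_chr(substr(mono, 131, 150)))
  prods2 <- in_silico_pcr(strrep(mono, 2), pair_manual)
  expect_equal(prods2, (1000 - 900) + 150)

  expect_error(in_silico_pcr(mono, list(forward = "ACGTACGTAC",
                                        reverse = pair$reverse$seq)),
               "15 bp")
})

test_that("percent identity is symmetric and tracks divergence", {
  set.seed(56)
  a <- random_dna(100)
  expect_equal(percent_identity(a, a), 100)

  b <- a
  substr(b, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(a, 40, 40))[1]
  expect_equal(percent_identity(a, b), 99)

  cons <- random_dna(963)
  clone <- satkit:::.mutate_chr(cons, 0.05)
  pid <- percent_identity(clone, cons)
  expect_gte(pid, 92)
  expect_lte(pid, 99)
  expect_equal(percent_identity(clone, cons), percent_identity(cons, clone))
})
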