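test_that("haplotype frequency follows the genotype-count formula", {
  expect_equal(haplotypeFrequency(7, 0, 0), 1)
  expect_equal(haplotypeFrequency(1, 2, 7), 0.2)
  expect_equal(haplotypeFrequency(0, 0, 5), 0)
  expect_error(haplotypeFrequency(0, 0, 0), "all-zero")
  expect_error(haplotypeFrequency(-1, 2, 7), "negative")
})

test_that("HWE statistic is squared-Pearson on the three genotype classes", {
  # counts exactly at expectation -> 0
  n <- 100; p <- 0.4; q <- 0.6
  expect_equal(hweChisq(p^2 * n, 2 * p * q * n, q^2 * n), 0)
  # worked case: (10, 0, 90) has p = 0.1, exp = (1, 18, 81), X2 = 100
  expect_equal(hweChisq(10, 0, 90), 100)
  # monomorphic defined as 0
  expect_equal(hweChisq(50, 0, 0), 0)

  # identity with an independent Pearson oracle on random count triples
  cnt <- random_counts(1000, seed = 11)
  for (i in seq_len(nrow(cnt))) {
    o <- cnt[i, ]
    p <- (2 * o[1] + o[2]) / (2 * sum(o))
    if (p <= 0 || p >= 1) next
    oracle <- suppressWarnings(
      chisq.test(o, p = c(p^2, 2 * p * (1 - p), (1 - p)^2))$statistic)
    expect_equal(hweChisq(o[1], o[2], o[3]), unname(oracle),
                 tolerance = 1e-10)
  }
})

test_that("HWE test is calibrated against its chi-squared(1) reference", {
  # empirical exceedance of 3.84 under HWE sampling ~ 5%
  set.seed(21)
  n <- 300; p <- 0.3
  draws <- rmultinom(10000, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  x2 <- hweChisq(draws[1, ], draws[2, ], draws[3, ])
  exceed <- mean(x2 > qchisq(0.95, 1))
  expect_lt(abs(exceed - 0.05), 0.015)

  # the QC threshold 24 (P < 1e-6) is essentially never crossed under HWE
  draws <- rmultinom(100000, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  x2 <- hweChisq(draws[1, ], draws[2, ], draws[3, ])
  expect_lte(sum(x2 > 24), 2)
})

test_that("haplotype calling tallies AA/Aa/aa against the pooled alternative", {
  p <- toy_panel()
  w <- data.frame(chrom = "1", size_cm = 0.25, first_idx = 1L, last_idx = 2L,
                  start_bp = 100L, end_bp = 200L, start_cm = 0, n_snps = 2L)
  al <- callHaplotypes(p, w)
  # haploid strings: ind1 {01,01} ind2 {01,11} ind3 {00,01} ind4 {10,10}
  a01 <- al[al$allele_string == "01", ]
  expect_equal(a01$obs_AA, 1L)
  expect_equal(a01$obs_Aa, 2L)
  expect_equal(a01$obs_aa, 1L)
  expect_equal(a01$p, 4 / 8)
  # all individuals identical and homozygous -> single allele, p = 1
  H <- matrix(0L, 8, 2)
  mono <- PhasedPanel(panelSnps(p)[1:2, ], panelIndividuals(p), H)
  al1 <- callHaplotypes(mono, w)
  expect_equal(nrow(al1), 1L)
  expect_equal(al1$obs_AA, 4L)
  expect_equal(al1$p, 1)
})

test_that("frequencies and dosages are conserved across a window's alleles", {
  sim <- small_sim()
  w <- windows_for(sim$panel)[c(1, 5, 9), ]
  n <- nIndividuals(sim$panel)
  for (i in 1:3) {
    al <- callHaplotypes(sim$panel, w[i, ])
    expect_equal(sum(al$p), 1)
    expect_equal(sum(2 * al$obs_AA + al$obs_Aa), 2 * n)
    dose <- sapply(al$allele_string, function(s)
      haplotypeDosage(sim$panel, w[i, ], s))
    expect_equal(unname(rowSums(dose)), rep(2, n))
  }
})

test_that("QC merges on frequency bounds and the strict HWE cut", {
  al <- data.frame(allele_string = c("a", "b", "c", "d", "e"),
                   p = c(0.004, 0.005, 0.5, 0.996, 0.995),
                   x2 = c(0, 0, 0, 0, 0))
  qc <- qcFilter(al)
  expect_equal(qc$merged, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  al2 <- data.frame(allele_string = c("a", "b"), p = c(0.5, 0.5),
                    x2 = c(25, 24))
  expect_equal(qcFilter(al2)$merged, c(TRUE, FALSE))
  # all alleles rare -> everything merged, nothing testable
  al3 <- data.frame(allele_string = letters[1:3], p = rep(0.001, 3),
                    x2 = rep(0, 3))
  expect_true(all(qcFilter(al3)$merged))
})

test_that("dosage counts exact haploid matches and validates length", {
  p <- toy_panel()
  w <- data.frame(chrom = "1", size_cm = 0.25, first_idx = 1L, last_idx = 2L,
                  start_bp = 100L, end_bp = 200L, start_cm = 0, n_snps = 2L)
  expect_equal(haplotypeDosage(p, w, "01"), c(2L, 1L, 1L, 0L))
  expect_equal(haplotypeDosage(p, w, "10"), c(0L, 0L, 0L, 2L))
  expect_error(haplotypeDosage(p, w, "010"), "does not match")
  # grouped extraction agrees with row-by-row calls
  al <- data.frame(first_idx = c(1L, 1L, 3L), last_idx = c(2L, 2L, 4L),
                   allele_string = c("01", "11", "01"))
  grouped <- haplotypeDosages(p, al)
  for (i in 1:3) {
    wi <- list(first_idx = al$first_idx[i], last_idx = al$last_idx[i])
    expect_identical(grouped[[i]],
                     haplotypeDosage(p, wi, al$allele_string[i]))
  }
})
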