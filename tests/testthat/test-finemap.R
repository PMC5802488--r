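# minimal scan-results frame for boundary-refinement tests
mk_results <- function(first, last, allele, beta, p, chrom = "6",
                       size = 0.5, window_id = seq_along(first)) {
  data.frame(window_id = window_id, chrom = chrom, window_cm = size,
             first_idx = first, last_idx = last, allele_string = allele,
             beta = beta, p = p, stringsAsFactors = FALSE)
}

test_that("candidate pairs need overlap, significance and concordant direction", {
  # disjoint windows: no pair
  r <- mk_results(c(1L, 100L), c(28L, 127L),
                  c(strrep("0", 28), strrep("1", 28)), c(0.1, 0.1),
                  c(1e-5, 1e-5))
  expect_equal(nrow(findCandidatePairs(r)), 0L)
  # identical windows, opposite signs: no pair
  r <- mk_results(c(1L, 1L), c(28L, 28L),
                  c(strrep("0", 28), strrep("1", 28)), c(0.1, -0.1),
                  c(1e-5, 1e-5))
  expect_equal(nrow(findCandidatePairs(r)), 0L)
  # P threshold is strict
  r$beta <- c(0.1, 0.1)
  r$p <- c(1e-5, 1e-3)
  expect_equal(nrow(findCandidatePairs(r, p_thresh = 1e-3)), 0L)

  # overlapping trio: pairs equal a brute-force all-pairs oracle
  r <- mk_results(c(1L, 8L, 15L), c(20L, 27L, 34L),
                  c(strrep("01", 10), strrep("01", 10), strrep("01", 10)),
                  c(0.2, 0.15, -0.1), c(1e-4, 1e-4, 1e-4))
  got <- findCandidatePairs(r)
  oracle <- list()
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- min(r$last_idx[i], r$last_idx[j]) -
      max(r$first_idx[i], r$first_idx[j]) + 1L
    if (ov >= 5 && r$p[i] < 1e-3 && r$p[j] < 1e-3 &&
        sign(r$beta[i]) == sign(r$beta[j]))
      oracle[[length(oracle) + 1L]] <- c(i, j)
  }
  expect_equal(nrow(got), length(oracle))   # only the (1,2) pair survives
  expect_equal(unlist(lapply(oracle, `[`, 1)), got$i)
})

test_that("shared consecutive regions equal a longest-common-run oracle", {
  # the 28-SNP pair differing at the first SNP refines to 27 SNPs
  a <- paste0("1", strrep("0", 27))
  b <- strrep("0", 28)
  r <- mk_results(c(1L, 1L), c(28L, 28L), c(a, b), c(0.2, 0.2), c(1e-4, 1e-4))
  pr <- findCandidatePairs(r)
  reg <- sharedConsecutiveRegion(r, pr[1, ])
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$first_idx, 2L)
  expect_equal(reg$last_idx, 28L)
  expect_equal(nchar(reg$allele_string), 27L)

  # identical alleles refine to themselves
  r2 <- mk_results(c(1L, 1L), c(28L, 28L), c(b, b), c(0.2, 0.2),
                   c(1e-4, 1e-4))
  reg2 <- sharedConsecutiveRegion(r2, findCandidatePairs(r2)[1, ])
  expect_equal(reg2$allele_string, b)

  # no run of 5 agreeing SNPs: nothing returned
  a4 <- "101010101"
  b4 <- "010101010"
  r3 <- mk_results(c(1L, 1L), c(9L, 9L), c(a4, b4), c(0.2, 0.2),
                   c(1e-4, 1e-4))
  expect_null(sharedConsecutiveRegion(r3, findCandidatePairs(r3)[1, ]))

  # random pairs against a brute-force longest-run oracle
  set.seed(51)
  for (rep in 1:2000) {
    L <- sample(6:40, 1)
    s1 <- paste(sample(0:1, L, TRUE), collapse = "")
    s2 <- paste(sample(0:1, L, TRUE), collapse = "")
    rr <- mk_results(c(1L, 1L), c(L, L), c(s1, s2), c(1, 1), c(1e-4, 1e-4))
    pair <- data.frame(i = 1L, j = 2L, ov_first = 1L, ov_last = L)
    got <- sharedConsecutiveRegion(rr, pair, all_runs = FALSE)
    agree <- strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]]
    runs <- rle(agree)
    best <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (best < 5L) {
      expect_null(got)
    } else {
      expect_equal(nchar(got$allele_string), best)
      expect_identical(substr(s1, got$first_idx, got$last_idx),
                       got$allele_string)
    }
  }
})

test_that("refined haplotypes are re-tested with the scan's mixed model", {
  set.seed(52)
  sim <- simulateCohort(simConfig(
    n_individuals = 300L, n_snps = 400L, map_length_cm = 4,
    causal = list(list(locus = 200L, target_freq = 0.15, beta = 0.8,
                       n_snps = 10L)),
    seed = 53L))
  w <- windows_for(sim$panel, 0.25)
  ctl <- catalogueHaplotypes(sim$panel, w)
  g <- grmPair(snpDosages(sim$panel), ids = panelIndividuals(sim$panel))
  sc <- scanHaplotypes(sim$panel, ctl, sim$pheno, g)
  fm <- fineMap(sim$panel, sc, p_thresh = 1e-2)
  expect_gt(nrow(fm), 0)
  # refinement stays inside the union of the parent windows and can only
  # pool carriers: refined frequency >= max of the parents'
  for (i in seq_len(nrow(fm))) {
    pi <- fm$parent_i[i]; pj <- fm$parent_j[i]
    expect_gte(fm$first_idx[i], min(sc$results$first_idx[c(pi, pj)]))
    expect_lte(fm$last_idx[i], max(sc$results$last_idx[c(pi, pj)]))
    expect_gte(fm$freq[i], max(sc$results$freq[c(pi, pj)]) - 1e-12)
  }
  # a refined allele identical to an original reproduces its P exactly
  r1 <- sc$results[which.min(sc$results$p), ]
  d <- haplotypeDosage(sim$panel, r1, r1$allele_string)
  tt <- testHaplotype(sc$ctx, d)
  expect_equal(tt$p, r1$p, tolerance = 1e-12)
})
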