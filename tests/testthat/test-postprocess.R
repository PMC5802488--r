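test_that("dosage r2 is the squared Pearson correlation", {
  expect_equal(ldR2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ldR2(c(1, 1, -1, -1), c(1, -1, 1, -1)), 0)
  expect_error(ldR2(rep(1, 4), c(0, 1, 2, 1)), "constant")
  set.seed(61)
  for (i in 1:50) {
    a <- rbinom(30, 2, 0.4); b <- rbinom(30, 2, 0.4)
    if (var(a) == 0 || var(b) == 0) next
    oracle <- (mean(a * b) - mean(a) * mean(b))^2 / (
      (mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
    expect_equal(ldR2(a, b), oracle, tolerance = 1e-12)
  }
})

# independent greedy-clump oracle (transitive assignment to the best index)
clump_oracle <- function(results, dosages, r2 = 0.4, kb = 1000) {
  n <- nrow(results)
  mid <- (results$start_bp + results$end_bp) / 2
  ord <- order(results$p, results$chrom, results$start_bp)
  cl <- rep(NA_integer_, n); idx <- integer(0)
  for (i in ord) {
    if (!is.na(cl[i])) next
    idx <- c(idx, i); cl[i] <- length(idx)
    for (j in seq_len(n)) {
      if (!is.na(cl[j]) || results$chrom[j] != results$chrom[i]) next
      if (abs(mid[j] - mid[i]) > kb * 1000) next
      if (cor(dosages[[i]], dosages[[j]])^2 >= r2) cl[j] <- cl[i]
    }
  }
  list(assignment = cl, n_independent = length(idx))
}

test_that("LD clumping matches a brute-force oracle and is order-invariant", {
  set.seed(62)
  n_hap <- 40
  base <- replicate(8, rbinom(60, 2, 0.3), simplify = FALSE)
  dos <- lapply(seq_len(n_hap), function(i) {
    b <- base[[sample(8, 1)]]
    flip <- rbinom(60, 1, 0.1)
    pmin(pmax(b + flip * sample(c(-1, 1), 60, TRUE), 0), 2)
  })
  res <- data.frame(chrom = sample(c("1", "2"), n_hap, TRUE),
                    start_bp = sample.int(5e6, n_hap),
                    p = runif(n_hap))
  res$end_bp <- res$start_bp + 1000L
  cr <- clumpResults(res, dos)
  or <- clump_oracle(res, dos)
  expect_equal(cr$n_independent, or$n_independent)
  expect_equal(cr$assignment, or$assignment)
  expect_equal(cr$bonferroni_alpha, 0.05 / cr$n_independent)
  # every haplotype in exactly one clump
  expect_false(anyNA(cr$assignment))

  # order invariance: a shuffled input yields the same partition of rows
  perm <- sample(n_hap)
  cr2 <- clumpResults(res[perm, ], dos[perm])
  norm <- function(members, assignment)
    sort(vapply(split(members, assignment),
                function(s) paste(sort(s), collapse = ","), character(1)))
  expect_identical(norm(seq_len(n_hap), cr$assignment),
                   norm(perm, cr2$assignment))

  # degenerate cases: identical dosages collapse to one clump
  d0 <- rbinom(50, 2, 0.5)
  r0 <- data.frame(chrom = "1", start_bp = 1:5 * 1000L,
                   end_bp = 1:5 * 1000L + 10L, p = runif(5))
  cr_same <- clumpResults(r0, rep(list(d0), 5))
  expect_equal(cr_same$n_independent, 1L)
  # uncorrelated dosages each form their own clump
  dA <- rep(c(0, 2), 25)
  dB <- rep(c(0, 0, 2, 2), length.out = 50)
  cr_ind <- clumpResults(r0[1:2, ], list(dA, dB))
  expect_equal(cr_ind$n_independent, 2L)
  expect_error(clumpResults(r0[0, ], list()), "empty")
})

test_that("genomic inflation is 1 under uniformity and scales with chi-squared", {
  p <- (seq_len(2000) - 0.5) / 2000
  expect_lt(abs(genomicInflation(p) - 1), 0.01)
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomicInflation(p2), 2 * genomicInflation(p),
               tolerance = 0.01)
  expect_warning(genomicInflation(runif(10)), "unstable")
})

test_that("inverse-variance meta-analysis satisfies its closed-form identities", {
  # two identical cohorts: same beta, se shrinks by sqrt(2)
  m <- ivwMeta(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, 0.1 / sqrt(2))
  # k equal cohorts shrink se by sqrt(k) exactly
  for (k in c(3, 5, 8)) {
    mk <- ivwMeta(rep(0.2, k), rep(0.07, k))
    expect_equal(mk$se, 0.07 / sqrt(k), tolerance = 1e-12)
  }
  # an infinitely noisy cohort contributes nothing
  m2 <- ivwMeta(c(0.3, 50), c(0.1, 1e6))
  expect_equal(m2$beta, 0.3, tolerance = 1e-6)
  # two-cohort worked case on the log-OR scale
  m3 <- ivwMeta(c(0.5188, 0.1310), c(0.0822, 0.0449))
  expect_lt(abs(m3$beta - 0.2200), 5e-4)
  expect_error(ivwMeta(c(0.1, 0.2), c(0.1, 0)), "non-positive")
  expect_error(ivwMeta(0.1, 0.1), "two cohorts")
})

test_that("printed OR/CI rows convert to log-OR and SE exactly", {
  expect_equal(orCiToBetaSe(1, exp(-1.959964), exp(1.959964)),
               c(beta = 0, se = 1), tolerance = 1e-10)
  b <- orCiToBetaSe(1.68, 1.42, 1.96)
  expect_equal(round(unname(b), 4), c(0.5188, 0.0822))
  # inverse of the exponentiation round-trips
  or_ <- 1.37; se <- 0.041; beta <- log(or_)
  rt <- orCiToBetaSe(or_, exp(beta - 1.959964 * se), exp(beta + 1.959964 * se))
  expect_equal(unname(rt), c(beta, se), tolerance = 1e-10)
  expect_error(orCiToBetaSe(1.2, 1.3, 1.4), "require")
})

test_that("allelic power is alpha at the null, monotone, and matches Monte Carlo", {
  expect_equal(allelicPower(1, 0.1, 0.146, 5000, 5000, alpha = 0.05), 0.05,
               tolerance = 1e-9)
  # monotone in grr, freq (below 0.5) and n
  p1 <- allelicPower(c(1.2, 1.5, 2), 0.05, 0.146, 2000, 2000)
  expect_true(all(diff(p1) > 0))
  p2 <- allelicPower(1.5, c(0.02, 0.05, 0.2), 0.146, 2000, 2000)
  expect_true(all(diff(p2) > 0))
  p3 <- vapply(c(500, 2000, 8000), function(n)
    allelicPower(1.5, 0.05, 0.146, n, n), numeric(1))
  expect_true(all(diff(p3) > 0))
  expect_error(allelicPower(0, 0.1, 0.146, 100, 100), "grr")

  # Monte-Carlo oracle: simulate allele counts and apply the same z-test
  mc_power <- function(grr, freq, K, nca, nco, alpha = 0.05, reps = 10000) {
    p_case <- freq * grr / (1 + freq * (grr - 1))
    p_ctrl <- (freq - K * p_case) / (1 - K)
    xa <- rbinom(reps, 2 * nca, p_case)
    xo <- rbinom(reps, 2 * nco, p_ctrl)
    pa <- xa / (2 * nca); po <- xo / (2 * nco)
    se <- sqrt(pa * (1 - pa) / (2 * nca) + po * (1 - po) / (2 * nco))
    z <- (pa - po) / se
    mean(abs(z) > qnorm(1 - alpha / 2), na.rm = TRUE)
  }
  set.seed(63)
  cases <- list(c(1.5, 0.05, 1000, 2000), c(1.3, 0.10, 3000, 3000),
                c(2.0, 0.02, 800, 1600))
  for (cs in cases) {
    an <- allelicPower(cs[1], cs[2], 0.146, cs[3], cs[4])
    mc <- mc_power(cs[1], cs[2], 0.146, cs[3], cs[4])
    expect_lt(abs(an - mc), 0.02)
  }
})
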