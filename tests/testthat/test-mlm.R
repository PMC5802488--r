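# block-diagonal family relationship matrix: fam families of size sz
block_grm <- function(fam, sz, r = 0.5) {
  n <- fam * sz
  G <- matrix(0, n, n)
  for (f in seq_len(fam)) {
    i <- ((f - 1) * sz + 1):(f * sz)
    G[i, i] <- r
  }
  diag(G) <- 1
  G
}

mvn_from <- function(G, s2) {
  as.numeric(crossprod(chol(G), rnorm(nrow(G)))) * sqrt(s2)
}

test_that("REML recovers simulated variance components without material bias", {
  set.seed(41)
  G <- block_grm(100, 5)
  n <- nrow(G)
  X <- cbind(1, rnorm(n))
  est <- replicate(200, {
    y <- as.numeric(X %*% c(0.2, 0.1)) + mvn_from(G, 0.5) + rnorm(n, 0, sqrt(0.5))
    varComponents(remlFit(y, X, list(G)))[1:2]
  })
  expect_lt(abs(mean(est["sigma2_u", ]) - 0.5), 0.05)
  expect_lt(abs(mean(est["sigma2_e", ]) - 0.5), 0.05)
})

test_that("REML on pure noise attributes almost nothing to the genomic term", {
  set.seed(42)
  # the boundary constraint makes sigma2_u-hat a folded distribution under
  # the null; its mean shrinks with the information, i.e. with cohort size
  G <- block_grm(200, 6)
  n <- nrow(G)
  X <- matrix(1, n, 1)
  su <- replicate(25, {
    y <- rnorm(n)
    varComponents(remlFit(y, X, list(G)))["sigma2_u"] / var(y)
  })
  expect_lte(mean(su), 0.05)
})

test_that("REML rejects degenerate inputs", {
  n <- 60
  G <- block_grm(12, 5)
  expect_error(remlFit(rep(1, n), matrix(1, n, 1), list(G)),
               "degenerate phenotype")
  expect_error(remlFit(rnorm(n), matrix(1, n, 1), list(diag(n))),
               "unidentifiable")
})

test_that("dense two-matrix REML agrees with the eigen single-matrix path", {
  set.seed(43)
  G <- block_grm(40, 5)
  n <- nrow(G)
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(0.1, 0.2)) + mvn_from(G, 0.4) + rnorm(n, 0, sqrt(0.6))
  f1 <- remlFit(y, X, list(G))
  # a fully redundant second matrix splits sigma2_u but cannot change the
  # model: restricted likelihood and total genetic variance must agree
  f2 <- remlFit(y, X, list(G, G))
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-3)
  expect_equal(varComponents(f1)[["sigma2_u"]],
               sum(varComponents(f2)[1:2]), tolerance = 0.05)

  # scan results identical when the second component is pinned to zero
  ctx1 <- scanContext(y, X, list(G), f1)
  f1b <- new("RemlFit",
             sigma2 = c(sigma2_u = varComponents(f1)[["sigma2_u"]],
                        sigma2_v = 0,
                        sigma2_e = varComponents(f1)[["sigma2_e"]]),
             loglik = f1@loglik, converged = TRUE, iterations = 1L,
             n = as.integer(n))
  ctx2 <- scanContext(y, X, list(G, matrix(0, n, n)), f1b)
  d <- rbinom(n, 2, 0.2)
  t1 <- testHaplotype(ctx1, d)
  t2 <- testHaplotype(ctx2, d)
  expect_equal(t1$beta, t2$beta, tolerance = 1e-8)
  expect_equal(t1$p, t2$p, tolerance = 1e-8)
})

test_that("the GLS Wald test recovers a planted observed-scale effect", {
  set.seed(44)
  G <- block_grm(80, 5)
  n <- nrow(G)
  X <- cbind(1, rnorm(n))
  beta_true <- 0.3
  est <- replicate(50, {
    d <- rbinom(n, 2, 0.2)
    y <- as.numeric(X %*% c(0.2, 0.1)) + beta_true * d +
      mvn_from(G, 0.3) + rnorm(n, 0, sqrt(0.7))
    fit <- remlFit(y, X, list(G))
    ctx <- scanContext(y, X, list(G), fit)
    testHaplotype(ctx, d)$beta
  })
  # mean recovery within 3 standard errors of the replicate mean
  expect_lt(abs(mean(est) - beta_true), 3 * sd(est) / sqrt(length(est)) + 0.01)
})

test_that("tests skip constant dosages and reject aliased covariates", {
  set.seed(45)
  G <- block_grm(20, 5)
  n <- nrow(G)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n) + mvn_from(G, 0.3)
  fit <- remlFit(y, X, list(G))
  ctx <- scanContext(y, X, list(G), fit)
  expect_true(testHaplotype(ctx, rep(1, n))$skipped)
  expect_error(testHaplotype(ctx, 2 * X[, 2] + 3), "aliased")
})

test_that("scan P-values are invariant to affine covariate rescaling", {
  set.seed(46)
  G <- block_grm(40, 5)
  n <- nrow(G)
  age <- runif(n, 18, 99)
  ph <- data.frame(iid = sprintf("i%03d", 1:n), y = rbinom(n, 1, 0.3),
                   sex = rbinom(n, 1, 0.5), age = age)
  X1 <- designMatrix(ph)
  ph2 <- ph
  ph2$age <- (age - 50) / 10
  X2 <- designMatrix(ph2)
  y <- ph$y
  d <- rbinom(n, 2, 0.3)
  f1 <- remlFit(y, X1, list(G))
  f2 <- remlFit(y, X2, list(G))
  p1 <- testHaplotype(scanContext(y, X1, list(G), f1), d)$p
  p2 <- testHaplotype(scanContext(y, X2, list(G), f2), d)$p
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("design matrix drops aliased columns deterministically", {
  ph <- data.frame(iid = c("a", "b", "c", "d"), y = c(0, 1, 0, 1),
                   sex = c(0, 1, 0, 1), age = c(30, 40, 50, 60),
                   batch = c("x", "x", "y", "y"))
  X <- designMatrix(ph, c("sex", "age", "age2", "batch"))
  expect_equal(qr(X)$rank, ncol(X))
  expect_equal(colnames(X)[1], "intercept")
  # single-level factor contributes nothing
  ph$centre <- "only"
  X2 <- designMatrix(ph, c("sex", "centre"))
  expect_equal(colnames(X2), c("intercept", "sex"))
})

test_that("observed-scale OR conversion tracks a logistic oracle", {
  expect_equal(unname(betaToOr(0, 0.01, 0.3)["or_"]), 1)
  # monotone in beta
  ors <- vapply(c(0.01, 0.05, 0.1), function(b)
    betaToOr(b, 0.01, 0.3)[["or_"]], numeric(1))
  expect_true(all(diff(ors) > 0))

  set.seed(47)
  n <- 4000
  d <- rbinom(n, 2, 0.3)
  eta <- -1.2 + 0.35 * d
  y <- rbinom(n, 1, plogis(eta))
  X <- matrix(1, n, 1)
  lin <- lm(y ~ d)
  b <- coef(lin)["d"]; se <- summary(lin)$coefficients["d", 2]
  conv <- betaToOr(b, se, mean(y))
  orc <- logisticOr(y, d, X)
  expect_lt(abs(conv[["or_"]] - orc[["or_"]]) / orc[["or_"]], 0.05)
})

test_that("variance explained follows 2p(1-p)b^2 and matches regression R2", {
  expect_equal(varianceExplained(0.5, 0, denom = 1)$raw, 0)
  expect_equal(varianceExplained(0.5, 1, denom = 1)$fraction, 0.5)
  expect_error(varianceExplained(0, 1), "in \\(0,1\\)")
  set.seed(48)
  n <- 20000; p <- 0.3; b <- 0.1
  d <- rbinom(n, 2, p)
  y <- b * d + rnorm(n)
  fit <- lm(y ~ d)
  r2 <- summary(fit)$r.squared
  # oracle identity holds at the realized frequency and fitted effect
  ve <- varianceExplained(mean(d) / 2, coef(fit)["d"],
                          denom = var(y))$fraction
  expect_lt(abs(ve - r2) / r2, 0.1)
})
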