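#' Fixed-effect design matrix for the association model
#'
#' Builds the standard covariate design: intercept, sex, age, age squared,
#' and factor expansions of optional batch and centre columns.  Aliased
#' (linearly dependent) columns are dropped deterministically, later
#' columns first.
#'
#' @param pheno phenotype table (see \code{\link{readPhenotypes}}).
#' @param covariates character vector of covariate column names to include
#'   beyond the intercept; \code{"age2"} expands to age squared; columns
#'   that are non-numeric (or \code{batch}/\code{centre}) enter as factors.
#' @return numeric design matrix with one row per phenotype record.
#' @export
designMatrix <- function(pheno, covariates = c("sex", "age", "age2")) {
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    if (cv == "age2") {
      X <- cbind(X, age2 = pheno$age^2)
    } else if (!cv %in% names(pheno)) {
      stop("covariate not in phenotype table: ", cv)
    } else if (is.numeric(pheno[[cv]]) && !cv %in% c("batch", "centre")) {
      v <- matrix(pheno[[cv]], ncol = 1, dimnames = list(NULL, cv))
      X <- cbind(X, v)
    } else {
      f <- factor(pheno[[cv]])
      if (nlevels(f) > 1) {
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    X <- X[, keep, drop = FALSE]
  }
  X
}

.chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V2 <- V + diag(1e-6 * mean(diag(V)), nrow(V))
    ch <- tryCatch(chol(V2), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix not positive definite after jitter")
  }
  ch
}

#' REML variance components by average information with EM fallback
#'
#' Fits the linear mixed model y = Xb + sum_k u_k + e with
#' Var(u_k) = sigma2_k K_k and Var(e) = sigma2_e I by restricted maximum
#' likelihood.  Updates use the average-information (AI) algorithm; when an
#' AI step would leave the parameter space or decrease the restricted
#' likelihood, an EM step is taken instead.  Components are constrained
#' non-negative (pinned to a small floor at the boundary).
#'
#' The binary trait is analysed on the observed 0/1 scale: y enters as a
#' numeric vector and the model is linear, the standard approach for mixed
#' linear model association scans of case-control data.
#'
#' @param y numeric response (binary 0/1 for the association setting).
#' @param X fixed-effect design matrix (from \code{\link{designMatrix}}).
#' @param K list of relationship matrices, one per genomic random effect
#'   (e.g. \code{list(G)} or \code{list(G, Gt)}); the residual identity
#'   term is implicit.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param max_iter iteration budget.
#' @param verbose print the component trajectory.
#' @return a \linkS4class{RemlFit}; component names are \code{sigma2_u}
#'   (first matrix), \code{sigma2_v} (second, if any) and \code{sigma2_e}.
#' @export
remlFit <- function(y, X, K, tol = 1e-8, max_iter = 200L, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L || var(y) == 0) stop("degenerate phenotype: y is constant")
  if (!is.list(K)) K <- list(K)
  K <- lapply(K, function(k) as.matrix(k))
  for (k in K) {
    if (!all(dim(k) == n)) stop("relationship matrix dimension mismatch")
    if (max(abs(k - diag(n))) < 1e-12)
      stop("unidentifiable: relationship matrix is the identity (aliased with residual)")
  }
  if (length(K) == 1L)
    return(.remlFitEigen(y, X, K[[1]], tol = tol, max_iter = max_iter,
                         verbose = verbose))
  r <- length(K)
  Vlist <- c(K, list(diag(n)))
  vy <- var(y)
  theta <- rep(vy / (r + 1), r + 1)
  floor_ <- 1e-8 * vy

  obj <- function(theta) {
    V <- diag(theta[r + 1], n)
    for (k in seq_len(r)) V <- V + theta[k] * Vlist[[k]]
    ch <- .chol_safe(V)
    logdetV <- 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    XVX <- crossprod(X, VX)
    chx <- chol(XVX)
    logdetX <- 2 * sum(log(diag(chx)))
    XVXi <- chol2inv(chx)
    Py <- Vinv %*% y - VX %*% (XVXi %*% crossprod(VX, y))
    ll <- -0.5 * (logdetV + logdetX + sum(y * Py))
    list(ll = ll, Vinv = Vinv, VX = VX, XVXi = XVXi, Py = as.numeric(Py))
  }

  st <- obj(theta)
  ll_old <- st$ll
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # P M for each component via P = Vinv - VX XVXi VX'
    PV <- lapply(Vlist, function(Vk) {
      VkP <- st$Vinv %*% Vk - st$VX %*% (st$XVXi %*% crossprod(st$VX, Vk))
      VkP
    })
    Pyv <- st$Py
    PVPy <- lapply(Vlist, function(Vk) {
      w <- Vk %*% Pyv
      as.numeric(st$Vinv %*% w - st$VX %*% (st$XVXi %*% crossprod(st$VX, w)))
    })
    score <- vapply(seq_len(r + 1), function(k)
      -0.5 * (sum(diag(PV[[k]])) - sum(Pyv * (Vlist[[k]] %*% Pyv))),
      numeric(1))
    AI <- matrix(0, r + 1, r + 1)
    for (k in seq_len(r + 1)) for (l in k:(r + 1)) {
      AI[k, l] <- AI[l, k] <-
        0.5 * sum((Vlist[[k]] %*% Pyv) * PVPy[[l]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    cand <- if (is.null(step)) rep(-1, r + 1) else theta + step
    used_em <- FALSE
    if (any(cand < 0)) {
      # EM update, guaranteed in the parameter space
      cand <- vapply(seq_len(r + 1), function(k)
        theta[k] + theta[k]^2 *
          (sum(Pyv * (Vlist[[k]] %*% Pyv)) - sum(diag(PV[[k]]))) / n,
        numeric(1))
      used_em <- TRUE
    }
    cand <- pmax(cand, floor_)
    st_new <- obj(cand)
    if (!used_em && st_new$ll < ll_old - 1e-10) {
      # AI overshoot: halve towards the current point, then EM as last resort
      ok <- FALSE
      for (h in 1:5) {
        cand <- pmax(theta + (cand - theta) / 2, floor_)
        st_new <- obj(cand)
        if (st_new$ll >= ll_old - 1e-10) { ok <- TRUE; break }
      }
      if (!ok) {
        cand <- pmax(vapply(seq_len(r + 1), function(k)
          theta[k] + theta[k]^2 *
            (sum(Pyv * (Vlist[[k]] %*% Pyv)) - sum(diag(PV[[k]]))) / n,
          numeric(1)), floor_)
        st_new <- obj(cand)
      }
    }
    if (verbose)
      message(sprintf("iter %d  ll %.8f  theta %s", it, st_new$ll,
                      paste(signif(cand, 4), collapse = " ")))
    dll <- abs(st_new$ll - ll_old)
    theta <- cand
    st <- st_new
    ll_old <- st$ll
    if (dll < tol) { converged <- TRUE; break }
  }
  nm <- c(if (r >= 1) "sigma2_u", if (r >= 2) "sigma2_v",
          if (r >= 3) paste0("sigma2_k", 3:r), "sigma2_e")
  new("RemlFit", sigma2 = setNames(theta, nm), loglik = ll_old,
      converged = converged, iterations = it, n = as.integer(n))
}

# Single-relationship-matrix REML in the eigenbasis of K: after rotating
# y and X by the eigenvectors, V is diagonal and every iteration costs
# O(n p^2) instead of O(n^3) (the EMMA device).  Same AI + EM-fallback
# scheme as the dense path; results agree to the convergence tolerance.
.remlFitEigen <- function(y, X, K1, tol = 1e-8, max_iter = 200L,
                          verbose = FALSE) {
  n <- length(y)
  eg <- eigen(K1, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  vy <- var(y)
  theta <- rep(vy / 2, 2)  # (sigma2_u, sigma2_e)
  floor_ <- 1e-8 * vy
  Mdiag <- list(lam, rep(1, n))

  obj <- function(theta) {
    dv <- theta[1] * lam + theta[2]
    if (any(dv <= 0)) return(list(ll = -Inf))
    iv <- 1 / dv
    XtV <- Xt * iv
    XVX <- crossprod(Xt, XtV)
    chx <- chol(XVX)
    XVXi <- chol2inv(chx)
    bhat <- XVXi %*% crossprod(XtV, yt)
    Py <- iv * (yt - as.numeric(Xt %*% bhat))
    ll <- -0.5 * (sum(log(dv)) + 2 * sum(log(diag(chx))) + sum(yt * Py))
    list(ll = ll, iv = iv, XtV = XtV, XVXi = XVXi, Py = Py)
  }
  st <- obj(theta)
  ll_old <- st$ll
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Py <- st$Py
    # tr(P M) for diagonal M: sum(m * iv) - tr(XVXi * X' (m iv^2) X)
    trPM <- vapply(Mdiag, function(m) {
      sum(m * st$iv) - sum(st$XVXi * crossprod(Xt, Xt * (m * st$iv^2)))
    }, numeric(1))
    PMPy <- lapply(Mdiag, function(m) {
      v <- m * Py
      as.numeric(st$iv * v - st$XtV %*% (st$XVXi %*% crossprod(st$XtV, v)))
    })
    yPMPy <- vapply(seq_len(2), function(k) sum(Py * Mdiag[[k]] * Py),
                    numeric(1))
    score <- -0.5 * (trPM - yPMPy)
    AI <- matrix(0, 2, 2)
    for (k in 1:2) for (l in k:2)
      AI[k, l] <- AI[l, k] <- 0.5 * sum((Mdiag[[k]] * Py) * PMPy[[l]])
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    cand <- if (is.null(step)) rep(-1, 2) else theta + step
    used_em <- FALSE
    if (any(cand < 0)) {
      cand <- theta + theta^2 * (yPMPy - trPM) / n
      used_em <- TRUE
    }
    cand <- pmax(cand, floor_)
    st_new <- obj(cand)
    if (!used_em && st_new$ll < ll_old - 1e-10) {
      ok <- FALSE
      for (h in 1:5) {
        cand <- pmax(theta + (cand - theta) / 2, floor_)
        st_new <- obj(cand)
        if (st_new$ll >= ll_old - 1e-10) { ok <- TRUE; break }
      }
      if (!ok) {
        cand <- pmax(theta + theta^2 * (yPMPy - trPM) / n, floor_)
        st_new <- obj(cand)
      }
    }
    if (verbose)
      message(sprintf("iter %d  ll %.8f  theta %s", it, st_new$ll,
                      paste(signif(cand, 4), collapse = " ")))
    dll <- abs(st_new$ll - ll_old)
    theta <- cand
    st <- st_new
    ll_old <- st$ll
    if (dll < tol) { converged <- TRUE; break }
  }
  new("RemlFit", sigma2 = setNames(theta, c("sigma2_u", "sigma2_e")),
      loglik = ll_old, converged = converged, iterations = it,
      n = as.integer(n))
}

#' Precompute the GLS projection for a haplotype scan
#'
#' Forms V = sigma2_u G [+ sigma2_v Gt] + sigma2_e I from a null-model REML
#' fit, factorizes it once, and caches the pieces needed to test any number
#' of haplotype dosages by generalized least squares with V held fixed
#' (the MLMA convention: variance components are estimated once under the
#' null and reused for every test).
#'
#' @param y numeric 0/1 response.
#' @param X covariate design (no haplotype column).
#' @param K list of relationship matrices matching the fit.
#' @param fit \linkS4class{RemlFit} from \code{\link{remlFit}} on the same
#'   y, X, K.
#' @return an object of class \code{haploscan_scan_ctx} for
#'   \code{\link{testHaplotype}}.
#' @export
scanContext <- function(y, X, K, fit) {
  y <- as.numeric(y)
  n <- length(y)
  if (!is.list(K)) K <- list(K)
  th <- varComponents(fit)
  V <- diag(th[length(th)], n)
  for (k in seq_along(K)) V <- V + th[k] * as.matrix(K[[k]])
  ch <- .chol_safe(V)
  Vinv <- chol2inv(ch)
  VX <- Vinv %*% X
  XVXi <- chol2inv(chol(crossprod(X, VX)))
  Py <- as.numeric(Vinv %*% y - VX %*% (XVXi %*% crossprod(VX, y)))
  structure(list(Vinv = Vinv, VX = VX, XVXi = XVXi, Py = Py, y = y, X = X,
                 n = n, case_fraction = mean(y)),
            class = "haploscan_scan_ctx")
}

#' Wald test of one haplotype dosage
#'
#' Generalized-least-squares Wald test of the dosage coefficient with the
#' null-model covariance held fixed.  Effects are on the observed 0/1
#' scale; \code{\link{betaToOr}} converts to an odds ratio.
#'
#' @param ctx scan context from \code{\link{scanContext}}.
#' @param dosage numeric dosage vector (0/1/2 per individual).
#' @return list with \code{beta}, \code{se}, \code{z}, \code{p}; or a
#'   \code{skipped} marker with a reason when the dosage is constant.
#' @export
testHaplotype <- function(ctx, dosage) {
  d <- as.numeric(dosage)
  if (length(d) != ctx$n) stop("dosage length mismatch")
  if (var(d) == 0)
    return(list(skipped = TRUE, reason = "monomorphic in analyzed set"))
  Pd <- as.numeric(ctx$Vinv %*% d -
                   ctx$VX %*% (ctx$XVXi %*% crossprod(ctx$VX, d)))
  dPd <- sum(d * Pd)
  if (dPd < 1e-10 * sum(d * d))
    stop("aliased covariate: dosage lies in the span of the fixed effects")
  beta <- sum(d * ctx$Py) / dPd
  se <- sqrt(1 / dPd)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  list(skipped = FALSE, beta = beta, se = se, z = z, p = max(p, .Machine$double.xmin))
}

#' Convert an observed-scale effect to an odds ratio
#'
#' First-order conversion of a linear-model effect on a 0/1 trait into a
#' log-odds effect: log(OR) = beta / (cf (1 - cf)) where cf is the sample
#' case fraction, with the 95\% CI transformed the same way.  Exact for
#' small effects; \code{\link{logisticOr}} provides a logistic-refit
#' cross-check.
#'
#' @param beta,se effect and standard error on the observed scale.
#' @param case_fraction proportion of cases among analysed individuals.
#' @param level confidence level (default 0.95).
#' @return named vector \code{or_}, \code{or_lo}, \code{or_hi}.
#' @export
betaToOr <- function(beta, se, case_fraction, level = 0.95) {
  if (any(case_fraction <= 0 | case_fraction >= 1))
    stop("case_fraction must be in (0,1)")
  beta <- unname(beta); se <- unname(se)
  zq <- qnorm(1 - (1 - level) / 2)
  sc <- case_fraction * (1 - case_fraction)
  lo <- beta / sc
  slo <- se / sc
  c(or_ = exp(lo), or_lo = exp(lo - zq * slo), or_hi = exp(lo + zq * slo))
}

#' Logistic-regression odds ratio (relatedness-ignoring cross-check)
#'
#' Plain logistic fit of y on dosage plus covariates.  Valid only as a
#' sanity cross-check in samples without strong family structure.
#'
#' @param y 0/1 response.
#' @param dosage haplotype dosage.
#' @param X covariate design including intercept.
#' @return named vector \code{or_}, \code{or_lo}, \code{or_hi}, \code{p}.
#' @export
logisticOr <- function(y, dosage, X) {
  fit <- stats::glm.fit(cbind(X, dosage = dosage), y,
                        family = stats::binomial())
  cf <- unname(fit$coefficients["dosage"])
  # SE from the Fisher information of the converged fit
  w <- fit$weights
  Xa <- cbind(X, dosage = dosage)
  I <- crossprod(Xa * sqrt(w))
  se <- sqrt(diag(solve(I)))[ncol(Xa)]
  z <- cf / se
  c(or_ = exp(cf), or_lo = exp(cf - 1.959964 * se),
    or_hi = exp(cf + 1.959964 * se), p = 2 * pnorm(-abs(z)))
}

#' Variance explained by a haplotype allele
#'
#' Population-level contribution of an allele with frequency p and additive
#' effect beta: raw = 2 p (1 - p) beta^2, optionally expressed as a
#' fraction of a caller-supplied denominator (phenotypic variance or the
#' summed genetic variance components).
#'
#' @param p allele frequency in (0, 1).
#' @param beta additive effect.
#' @param denom variance denominator; \code{NULL} to return only the raw
#'   contribution.
#' @return list with \code{raw} and (when \code{denom} given)
#'   \code{fraction}.
#' @export
varianceExplained <- function(p, beta, denom = NULL) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0,1)")
  raw <- 2 * p * (1 - p) * beta^2
  if (is.null(denom)) list(raw = raw)
  else list(raw = raw, fraction = raw / denom)
}

#' Mixed-model haplotype association scan
#'
#' End-to-end scan of a QC'd haplotype catalogue: fits the null mixed model
#' once (one or two GRMs), then Wald-tests every non-merged allele's dosage
#' with the null covariance held fixed.
#'
#' @param panel a \linkS4class{PhasedPanel} (cm assigned).
#' @param catalogue haplotype catalogue from
#'   \code{\link{catalogueHaplotypes}}.
#' @param pheno phenotype table aligned to the panel (rows are matched by
#'   \code{iid}).
#' @param grm a \linkS4class{GrmPair}, or a plain matrix for the
#'   single-GRM model.
#' @param two_grm fit both G and its thresholded companion (TRUE, the
#'   family-cohort model) or G alone (the population-cohort model).
#' @param covariates passed to \code{\link{designMatrix}}.
#' @param fit optional pre-computed \linkS4class{RemlFit} to reuse.
#' @return list with \code{results} (summary-statistics data.frame, one row
#'   per tested allele: window coordinates, allele string, freq, hwe_x2,
#'   beta, se, z, p, or_, or_lo, or_hi, var_explained, var_fraction),
#'   \code{fit} (the \linkS4class{RemlFit}), \code{lambda_gc},
#'   \code{case_fraction}, \code{n}, and \code{skipped} (alleles not
#'   testable, with reasons).
#' @export
scanHaplotypes <- function(panel, catalogue, pheno, grm, two_grm = TRUE,
                           covariates = c("sex", "age", "age2"), fit = NULL) {
  ord <- match(panelIndividuals(panel), pheno$iid)
  if (anyNA(ord)) stop("phenotype table missing panel individuals")
  pheno <- pheno[ord, , drop = FALSE]
  y <- as.numeric(pheno$y)
  X <- designMatrix(pheno, covariates)
  K <- if (is(grm, "GrmPair")) {
    if (two_grm) list(grm@G, as.matrix(grm@Gt)) else list(grm@G)
  } else list(as.matrix(grm))
  if (is.null(fit)) fit <- remlFit(y, X, K)
  ctx <- scanContext(y, X, K, fit)
  tested <- catalogue[!catalogue$merged, , drop = FALSE]
  vc <- varComponents(fit)
  gvar <- sum(vc[-length(vc)])
  pvar <- var(y)
  dos <- haplotypeDosages(panel, tested)
  D <- matrix(as.numeric(unlist(dos)), nrow = ctx$n)
  cs2 <- colSums(D^2)
  dvar <- cs2 - ctx$n * colMeans(D)^2
  # batched GLS: P d for every dosage column at once
  PD <- ctx$Vinv %*% D - ctx$VX %*% (ctx$XVXi %*% crossprod(ctx$VX, D))
  dPd <- colSums(D * PD)
  dPy <- as.numeric(crossprod(D, ctx$Py))
  ok <- dvar > 0 & dPd > 1e-10 * pmax(cs2, 1)
  reason <- ifelse(dvar == 0, "monomorphic in analyzed set",
                   "aliased covariate")
  skipped <- if (all(ok)) NULL else
    data.frame(window_id = tested$window_id[!ok],
               allele_string = tested$allele_string[!ok],
               reason = reason[!ok], stringsAsFactors = FALSE)
  beta <- dPy[ok] / dPd[ok]
  se <- sqrt(1 / dPd[ok])
  z <- beta / se
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  cf <- ctx$case_fraction
  sc <- cf * (1 - cf)
  zq <- qnorm(0.975)
  al <- tested[ok, , drop = FALSE]
  ve <- 2 * al$p * (1 - al$p) * beta^2
  res <- data.frame(
    window_id = al$window_id, chrom = al$chrom, start_bp = al$start_bp,
    end_bp = al$end_bp, window_cm = al$size_cm, first_idx = al$first_idx,
    last_idx = al$last_idx, allele_string = al$allele_string,
    freq = al$p, hwe_x2 = al$x2, beta = beta, se = se, z = z, p = p,
    or_ = exp(beta / sc), or_lo = exp((beta - zq * se) / sc),
    or_hi = exp((beta + zq * se) / sc), var_explained = ve,
    var_fraction = ve / pvar, var_fraction_genetic = ve / gvar,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  lam <- if (nrow(res) >= 100) genomicInflation(res$p) else NA_real_
  list(results = res, fit = fit, lambda_gc = lam,
       case_fraction = ctx$case_fraction, n = ctx$n,
       skipped = skipped, ctx = ctx)
}
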