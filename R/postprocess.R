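#' Squared correlation between two dosage vectors
#'
#' The LD measure used for clumping: squared Pearson correlation of
#' haplotype dosages across individuals.
#'
#' @param dosage_a,dosage_b equal-length numeric vectors, both
#'   non-constant.
#' @return r-squared in [0, 1].
#' @export
ldR2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stop("dosage length mismatch")
  if (var(dosage_a) == 0 || var(dosage_b) == 0)
    stop("constant dosage vector: r2 undefined")
  cor(dosage_a, dosage_b)^2
}

#' LD clumping of haplotype association results
#'
#' Greedy clumping in the PLINK style: results are ordered by ascending P
#' (ties by chromosome then start position), each still-unassigned
#' haplotype in turn becomes a clump index, and every unassigned haplotype
#' on the same chromosome within \code{distance_kb} of the index whose
#' dosage r-squared with the index reaches \code{r2_threshold} joins its
#' clump.  The number of clumps estimates the number of independently
#' segregating haplotypes, and 0.05 divided by that count is the Bonferroni
#' significance level.
#'
#' @param results scan results with \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{p} (rows index the dosage list).
#' @param dosages list of dosage vectors, one per result row.
#' @param r2_threshold r-squared at or above which a haplotype joins a
#'   clump (default 0.4).
#' @param distance_kb maximum index-to-member distance in kb, measured
#'   between window midpoints (default 1000).
#' @return list of class \code{haploscan_clumps}: \code{n_input},
#'   \code{n_independent}, \code{r2_threshold}, \code{bonferroni_alpha},
#'   \code{assignment} (clump id per input row), \code{index} (row of each
#'   clump's index haplotype).
#' @export
clumpResults <- function(results, dosages, r2_threshold = 0.4,
                         distance_kb = 1000) {
  n <- nrow(results)
  if (n == 0L) stop("empty results: nothing to clump")
  if (length(dosages) != n) stop("one dosage vector per result row required")
  mid <- (results$start_bp + results$end_bp) / 2
  ord <- order(results$p, results$chrom, results$start_bp)
  assignment <- rep(NA_integer_, n)
  index <- integer(0)
  for (i in ord) {
    if (!is.na(assignment[i])) next
    cl <- length(index) + 1L
    index[cl] <- i
    assignment[i] <- cl
    near <- which(is.na(assignment) & results$chrom == results$chrom[i] &
                  abs(mid - mid[i]) <= distance_kb * 1000)
    for (j in near) {
      if (ldR2(dosages[[i]], dosages[[j]]) >= r2_threshold)
        assignment[j] <- cl
    }
  }
  structure(list(n_input = n, n_independent = length(index),
                 r2_threshold = r2_threshold,
                 bonferroni_alpha = 0.05 / length(index),
                 assignment = assignment, index = index),
            class = "haploscan_clumps")
}

#' Genomic inflation factor
#'
#' Lambda-GC: the median of the 1-df chi-squared statistics implied by a
#' vector of P-values, divided by the theoretical null median
#' qchisq(0.5, 1) = 0.4549364.  Values near 1 indicate a calibrated scan.
#'
#' @param p_values vector of two-sided P-values (at least 100 for a stable
#'   median).
#' @return lambda-GC.
#' @export
genomicInflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100)
    warning("fewer than 100 P-values; lambda-GC is unstable")
  chi <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort effects with weights 1/se^2:
#' beta = sum(w b) / sum(w), se = 1/sqrt(sum(w)), two-sided normal P.
#' Performed on the log-OR scale when the inputs are log odds ratios.
#'
#' @param betas numeric vector of per-cohort effects (>= 2).
#' @param ses matching standard errors, all > 0.
#' @return list: \code{beta}, \code{se}, \code{z}, \code{p}, \code{or_},
#'   \code{or_lo}, \code{or_hi} (the OR fields exponentiate beta, valid
#'   when inputs are log-ORs), and the per-cohort \code{weights}.
#' @export
ivwMeta <- function(betas, ses) {
  if (length(betas) < 2L) stop("at least two cohorts required")
  if (length(ses) != length(betas)) stop("betas and ses must match")
  if (any(ses <= 0)) stop("non-positive standard error")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  list(beta = beta, se = se, z = z, p = p,
       or_ = exp(beta), or_lo = exp(beta - 1.959964 * se),
       or_hi = exp(beta + 1.959964 * se), weights = w)
}

#' Recover log-OR and SE from a printed OR with 95\% CI
#'
#' beta = ln(OR); se = (ln(hi) - ln(lo)) / (2 * 1.959964).  Used to
#' meta-analyze summary rows published as odds ratios with confidence
#' intervals.
#'
#' @param or_,lo,hi odds ratio and its 95\% CI bounds, 0 < lo <= or_ <= hi.
#' @return named vector \code{beta}, \code{se}.
#' @export
orCiToBetaSe <- function(or_, lo, hi) {
  if (any(!(lo > 0 & lo <= or_ & or_ <= hi)))
    stop("require 0 < lo <= or_ <= hi")
  c(beta = log(or_), se = (log(hi) - log(lo)) / (2 * 1.959964))
}

#' Analytic power of the allelic replication test
#'
#' Power to detect a risk haplotype in a case-control sample under a
#' multiplicative (per-allele) risk model with screened controls.  With
#' population haplotype frequency f, genotype relative risk GRR and
#' population prevalence K, the case-haplotype frequency is
#' \deqn{p_{case} = f\,GRR / (1 + f\,(GRR - 1))}
#' and the control frequency follows from decomposing the population
#' frequency, f = K p_case + (1 - K) p_ctrl.  Power is that of the 1-df
#' two-proportion allelic z-test comparing 2 n_case case chromosomes with
#' 2 n_control control chromosomes at two-sided level alpha.
#'
#' @param grr genotype relative risk (> 0).
#' @param freq population frequency of the risk haplotype, in (0, 1).
#' @param K population prevalence of the trait, in (0, 1).
#' @param n_case,n_control numbers of cases and (screened) controls.
#' @param alpha two-sided significance level.
#' @return power in [0, 1].
#' @export
allelicPower <- function(grr, freq, K, n_case, n_control, alpha = 0.05) {
  if (any(grr <= 0)) stop("grr must be > 0")
  if (any(freq <= 0 | freq >= 1)) stop("freq must be in (0,1)")
  if (any(K <= 0 | K >= 1)) stop("K must be in (0,1)")
  p_case <- freq * grr / (1 + freq * (grr - 1))
  p_ctrl <- (freq - K * p_case) / (1 - K)
  if (any(p_ctrl <= 0)) stop("control frequency non-positive at these inputs")
  d <- p_case - p_ctrl
  se_alt <- sqrt(p_case * (1 - p_case) / (2 * n_case) +
                 p_ctrl * (1 - p_ctrl) / (2 * n_control))
  zq <- qnorm(1 - alpha / 2)
  pnorm(abs(d) / se_alt - zq) + pnorm(-abs(d) / se_alt - zq)
}
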