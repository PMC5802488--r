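#' Haplotype allele frequency
#'
#' Frequency of haplotype allele A versus the pooled alternative a, from the
#' three diploid genotype class counts:
#' \deqn{p = (2\,obs(AA) + obs(Aa)) / (2\,(obs(AA) + obs(Aa) + obs(aa)))}
#'
#' @param obs_AA,obs_Aa,obs_aa non-negative genotype counts (vectorised).
#' @return frequency p in [0, 1].
#' @export
haplotypeFrequency <- function(obs_AA, obs_Aa, obs_aa) {
  n <- obs_AA + obs_Aa + obs_aa
  if (any(n == 0)) stop("all-zero genotype counts")
  if (any(c(obs_AA, obs_Aa, obs_aa) < 0)) stop("negative counts")
  (2 * obs_AA + obs_Aa) / (2 * n)
}

#' Hardy-Weinberg chi-squared statistic for a haplotype allele
#'
#' Pearson goodness-of-fit statistic over the three genotype classes
#' (AA, Aa, aa) against the expectations (p^2 n, 2pq n, q^2 n), on 1 degree
#' of freedom (three classes, one estimated frequency).  Defined as 0 when
#' the allele is monomorphic (p = 0 or 1), where HWE is vacuous.
#'
#' @inheritParams haplotypeFrequency
#' @return the chi-squared statistic (vectorised), always >= 0.
#' @export
hweChisq <- function(obs_AA, obs_Aa, obs_aa) {
  n <- obs_AA + obs_Aa + obs_aa
  if (any(n < 1)) stop("at least one observation required")
  p <- (2 * obs_AA + obs_Aa) / (2 * n)
  q <- 1 - p
  eAA <- p^2 * n; eAa <- 2 * p * q * n; eaa <- q^2 * n
  x2 <- ifelse(p <= 0 | p >= 1, 0,
               (obs_AA - eAA)^2 / eAA + (obs_Aa - eAa)^2 / eAa +
               (obs_aa - eaa)^2 / eaa)
  unname(x2)
}

#' Upper-tail probability of the HWE test statistic
#'
#' Convenience wrapper: P(X2 >= x2) under the 1-df chi-squared null, the
#' scale on which the QC cut-off (x2 > 24, P < 1e-6) is calibrated.
#'
#' @param x2 chi-squared statistic(s).
#' @return upper-tail probability.
#' @export
hweTailProb <- function(x2) pchisq(x2, df = 1, lower.tail = FALSE)

.window_strings <- function(panel, window) {
  H <- panelHaplotypes(panel)
  cols <- seq(window$first_idx, window$last_idx)
  sub <- H[, cols, drop = FALSE]
  do.call(paste0, as.data.frame(sub))
}

#' Enumerate haplotype alleles in a window
#'
#' Lists every distinct haploid allele string observed across the window's
#' SNP span and tallies, for each allele A, the diploid genotype classes
#' against the pooled alternative a: AA (both copies A), Aa (exactly one),
#' aa (neither).  Frequencies use all individuals; a founders-only frequency
#' is additionally reported when a founder indicator is supplied, for
#' comparison with catalogues computed on unrelated individuals.
#'
#' @param panel a \linkS4class{PhasedPanel} with cm assigned.
#' @param window one row of a \code{\link{tileWindows}} table (list or
#'   1-row data.frame).
#' @param founders optional logical vector (one per individual) marking
#'   unrelated/founder individuals.
#' @return data.frame with one row per allele: \code{allele_string},
#'   \code{obs_AA}, \code{obs_Aa}, \code{obs_aa}, \code{n}, \code{p},
#'   \code{q}, \code{x2}, and \code{p_founder} when \code{founders} given;
#'   ordered by decreasing p.
#' @export
callHaplotypes <- function(panel, window, founders = NULL) {
  s <- .window_strings(panel, window)
  n <- nIndividuals(panel)
  i1 <- seq(1L, 2L * n, by = 2L)
  a <- s[i1]; b <- s[i1 + 1L]
  alleles <- unique(s)
  obs_AA <- obs_Aa <- integer(length(alleles))
  for (k in seq_along(alleles)) {
    ma <- a == alleles[k]; mb <- b == alleles[k]
    obs_AA[k] <- sum(ma & mb)
    obs_Aa[k] <- sum(xor(ma, mb))
  }
  obs_aa <- n - obs_AA - obs_Aa
  p <- haplotypeFrequency(obs_AA, obs_Aa, obs_aa)
  res <- data.frame(allele_string = alleles, obs_AA = obs_AA, obs_Aa = obs_Aa,
                    obs_aa = obs_aa, n = n, p = p, q = 1 - p,
                    x2 = hweChisq(obs_AA, obs_Aa, obs_aa),
                    stringsAsFactors = FALSE)
  if (!is.null(founders)) {
    stopifnot(length(founders) == n)
    fh <- c(a[founders], b[founders])
    res$p_founder <- vapply(alleles, function(al) mean(fh == al), numeric(1))
  }
  res <- res[order(-res$p, res$allele_string), ]
  rownames(res) <- NULL
  res
}

#' QC filter for haplotype alleles
#'
#' Alleles with frequency outside [p_min, p_max] or with an HWE statistic
#' strictly above \code{x2_max} are flagged \code{merged}: they are not
#' tested themselves but remain part of the pooled alternative for every
#' tested allele.  Defaults reproduce the usual haplotype-GWAS screen
#' (p outside [0.005, 0.995] or X2 > 24, i.e. HWE P < 1e-6).
#'
#' @param alleles allele table from \code{\link{callHaplotypes}}.
#' @param p_min,p_max frequency bounds (inclusive: p == p_min is kept).
#' @param x2_max HWE bound (strict: x2 == x2_max is kept).
#' @return the allele table with a logical \code{merged} column; tested
#'   alleles are \code{merged == FALSE}.
#' @export
qcFilter <- function(alleles, p_min = 0.005, p_max = 0.995, x2_max = 24) {
  alleles$merged <- alleles$p < p_min | alleles$p > p_max | alleles$x2 > x2_max
  alleles
}

#' Haplotype dosage
#'
#' Per-individual count (0/1/2) of haploid copies exactly matching an
#' allele string over a window's SNP span.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param window one window row.
#' @param allele_string allele string over the window's SNPs (characters
#'   '0'/'1' in SNP order).
#' @return integer vector of dosages, one per individual.
#' @export
haplotypeDosage <- function(panel, window, allele_string) {
  m <- window$last_idx - window$first_idx + 1L
  if (nchar(allele_string) != m)
    stop("allele string length ", nchar(allele_string),
         " does not match window SNP count ", m)
  s <- .window_strings(panel, window)
  n <- nIndividuals(panel)
  i1 <- seq(1L, 2L * n, by = 2L)
  as.integer((s[i1] == allele_string) + (s[i1 + 1L] == allele_string))
}

#' Dosage vectors for many alleles, grouped by window
#'
#' Equivalent to calling \code{\link{haplotypeDosage}} row by row, but the
#' window's haploid strings are built once per distinct SNP span.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param alleles data.frame with columns \code{first_idx},
#'   \code{last_idx}, \code{allele_string} (catalogue or scan-result rows).
#' @return list of integer dosage vectors, one per row of \code{alleles}.
#' @export
haplotypeDosages <- function(panel, alleles) {
  n <- nIndividuals(panel)
  i1 <- seq(1L, 2L * n, by = 2L)
  out <- vector("list", nrow(alleles))
  key <- paste(alleles$first_idx, alleles$last_idx)
  for (k in unique(key)) {
    rows <- which(key == k)
    s <- .window_strings(panel, alleles[rows[1], ])
    a <- s[i1]; b <- s[i1 + 1L]
    for (r in rows) {
      al <- alleles$allele_string[r]
      out[[r]] <- as.integer((a == al) + (b == al))
    }
  }
  out
}

#' Catalogue haplotype alleles over many windows
#'
#' Runs \code{\link{callHaplotypes}} + \code{\link{qcFilter}} across a
#' window table, returning one long table keyed by window.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param windows window table from \code{\link{tileWindows}}.
#' @param founders optional founder indicator, see
#'   \code{\link{callHaplotypes}}.
#' @inheritParams qcFilter
#' @return data.frame: window columns (\code{window_id}, \code{chrom},
#'   \code{size_cm}, \code{first_idx}, \code{last_idx}, \code{start_bp},
#'   \code{end_bp}) followed by the allele columns of
#'   \code{callHaplotypes} and the \code{merged} flag.
#' @export
catalogueHaplotypes <- function(panel, windows, founders = NULL,
                                p_min = 0.005, p_max = 0.995, x2_max = 24) {
  out <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    al <- qcFilter(callHaplotypes(panel, win, founders),
                   p_min = p_min, p_max = p_max, x2_max = x2_max)
    out[[w]] <- cbind(data.frame(window_id = w, chrom = win$chrom,
                                 size_cm = win$size_cm,
                                 first_idx = win$first_idx,
                                 last_idx = win$last_idx,
                                 start_bp = win$start_bp,
                                 end_bp = win$end_bp,
                                 stringsAsFactors = FALSE),
                      al, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
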