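#' Candidate pairs of overlapping associated haplotypes
#'
#' Two haplotype alleles of the same window size class whose windows share
#' at least \code{min_shared} consecutive SNPs, each with scan P below
#' \code{p_thresh} and effects in the same direction, may tag one causal
#' variant; their shared region is a fine-mapping candidate.
#'
#' @param results scan results data.frame (from
#'   \code{\link{scanHaplotypes}}), requiring columns \code{window_id},
#'   \code{chrom}, \code{window_cm}, \code{first_idx}, \code{last_idx},
#'   \code{allele_string}, \code{beta}, \code{p}.
#' @param p_thresh candidate threshold (default 1e-3).
#' @param min_shared minimum shared consecutive SNPs for "directly
#'   overlapping" (default 5).
#' @return data.frame of pairs: indices \code{i}, \code{j} into
#'   \code{results} with the shared index range \code{ov_first},
#'   \code{ov_last}.
#' @export
findCandidatePairs <- function(results, p_thresh = 1e-3, min_shared = 5L) {
  cand <- which(results$p < p_thresh)
  out <- list()
  if (length(cand) >= 2) {
    for (a in seq_along(cand)[-length(cand)]) {
      for (b in (a + 1):length(cand)) {
        i <- cand[a]; j <- cand[b]
        if (results$chrom[i] != results$chrom[j]) next
        if (results$window_cm[i] != results$window_cm[j]) next
        if (results$window_id[i] == results$window_id[j] &&
            results$allele_string[i] == results$allele_string[j]) next
        if (sign(results$beta[i]) != sign(results$beta[j])) next
        f <- max(results$first_idx[i], results$first_idx[j])
        l <- min(results$last_idx[i], results$last_idx[j])
        if (l - f + 1L < min_shared) next
        out[[length(out) + 1L]] <-
          data.frame(i = i, j = j, ov_first = f, ov_last = l)
      }
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(),
                      ov_first = integer(), ov_last = integer()))
  do.call(rbind, out)
}

#' Longest shared consecutive region of two overlapping alleles
#'
#' Restricted to the SNP-index intersection of the two windows, finds the
#' longest run of consecutive SNPs at which the two allele strings agree.
#' The run becomes a refined haplotype when it spans at least
#' \code{min_len} SNPs.
#'
#' @param results scan results data.frame.
#' @param pair one row of \code{\link{findCandidatePairs}} output.
#' @param min_len minimum refined length in SNPs (default 5).
#' @param all_runs return every agreeing run of length >= \code{min_len}
#'   (each a candidate) rather than only the longest.
#' @return data.frame of refined alleles (possibly 0 rows): \code{chrom},
#'   \code{first_idx}, \code{last_idx}, \code{allele_string},
#'   \code{parent_i}, \code{parent_j}; or NULL when no run qualifies.
#' @export
sharedConsecutiveRegion <- function(results, pair, min_len = 5L,
                                    all_runs = TRUE) {
  i <- pair$i; j <- pair$j
  f <- pair$ov_first; l <- pair$ov_last
  si <- substr(results$allele_string[i],
               f - results$first_idx[i] + 1L, l - results$first_idx[i] + 1L)
  sj <- substr(results$allele_string[j],
               f - results$first_idx[j] + 1L, l - results$first_idx[j] + 1L)
  agree <- strsplit(si, "")[[1]] == strsplit(sj, "")[[1]]
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_len)
  if (!length(runs)) return(NULL)
  if (!all_runs) runs <- runs[which.max(r$lengths[runs])]
  out <- lapply(runs, function(k) {
    a <- f + starts[k] - 1L
    b <- f + ends[k] - 1L
    data.frame(chrom = results$chrom[i], first_idx = a, last_idx = b,
               allele_string = substr(results$allele_string[i],
                                      a - results$first_idx[i] + 1L,
                                      b - results$first_idx[i] + 1L),
               parent_i = i, parent_j = j, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fine-map overlapping associated haplotypes
#'
#' Full fine-mapping pass: find candidate pairs, extract shared consecutive
#' regions, deduplicate, and re-test each refined haplotype with the same
#' null-model covariance as the main scan, using all individuals.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param scan output of \code{\link{scanHaplotypes}} (the returned list).
#' @inheritParams findCandidatePairs
#' @param min_len minimum refined haplotype length in SNPs.
#' @return data.frame of refined-haplotype association results with
#'   parent-pair provenance (columns as the main scan plus
#'   \code{parent_i}, \code{parent_j}), or an empty data.frame.
#' @export
fineMap <- function(panel, scan, p_thresh = 1e-3, min_shared = 5L,
                    min_len = 5L) {
  results <- scan$results
  empty <- data.frame()
  if (!nrow(results)) return(empty)
  pairs <- findCandidatePairs(results, p_thresh, min_shared)
  if (!nrow(pairs)) return(empty)
  refined <- list()
  for (r in seq_len(nrow(pairs))) {
    reg <- sharedConsecutiveRegion(results, pairs[r, ], min_len = min_len)
    if (!is.null(reg)) refined[[length(refined) + 1L]] <- reg
  }
  if (!length(refined)) return(empty)
  refined <- do.call(rbind, refined)
  refined <- refined[!duplicated(refined[, c("chrom", "first_idx", "last_idx",
                                             "allele_string")]), , drop = FALSE]
  ctx <- scan$ctx
  sn <- panelSnps(panel)
  out <- list()
  for (r in seq_len(nrow(refined))) {
    rf <- refined[r, ]
    win <- list(first_idx = rf$first_idx, last_idx = rf$last_idx)
    d <- haplotypeDosage(panel, win, rf$allele_string)
    tt <- testHaplotype(ctx, d)
    if (tt$skipped) next
    nloc <- sum(d) / (2 * length(d))
    cnt <- tabulate(d + 1L, 3L)  # aa, Aa, AA
    orci <- betaToOr(tt$beta, tt$se, ctx$case_fraction)
    out[[length(out) + 1L]] <- data.frame(
      chrom = rf$chrom, start_bp = sn$bp[rf$first_idx],
      end_bp = sn$bp[rf$last_idx], window_cm = NA_real_,
      first_idx = rf$first_idx, last_idx = rf$last_idx,
      allele_string = rf$allele_string, freq = nloc,
      hwe_x2 = hweChisq(cnt[3], cnt[2], cnt[1]),
      beta = tt$beta, se = tt$se, z = tt$z, p = tt$p,
      or_ = orci[["or_"]], or_lo = orci[["or_lo"]], or_hi = orci[["or_hi"]],
      parent_i = rf$parent_i, parent_j = rf$parent_j,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
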