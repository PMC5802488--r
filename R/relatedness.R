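#' SNP-based genomic relationship matrix
#'
#' VanRaden-style GRM from hard-call alt-allele dosages:
#' \deqn{G_{jk} = \frac{1}{M} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' where \eqn{x_{ij}} is the 0/1/2 dosage of individual j at SNP i and
#' \eqn{p_i} the alt-allele frequency.  Monomorphic SNPs carry no
#' relationship information and are excluded with a warning.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns,
#'   entries 0/1/2.
#' @param allele_freqs optional per-SNP alt-allele frequencies used for
#'   centring and scaling; defaults to frequencies estimated from
#'   \code{dosages} (set e.g. founders-only estimates here to change the
#'   reference population).
#' @return symmetric n x n matrix.
#' @export
computeGrm <- function(dosages, allele_freqs = NULL) {
  X <- as.matrix(dosages)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(X) / 2
  if (length(allele_freqs) != ncol(X))
    stop("one allele frequency per SNP required")
  poly <- allele_freqs > 0 & allele_freqs < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from GRM")
    X <- X[, poly, drop = FALSE]
    allele_freqs <- allele_freqs[poly]
  }
  M <- ncol(X)
  if (M == 0L) stop("no polymorphic SNPs left for GRM")
  W <- sweep(X, 2, 2 * allele_freqs)
  W <- sweep(W, 2, sqrt(2 * allele_freqs * (1 - allele_freqs)), "/")
  G <- tcrossprod(W) / M
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  (G + t(G)) / 2
}

#' Threshold a GRM
#'
#' Returns a sparse copy of G in which off-diagonal entries strictly below
#' \code{cutoff} are set to 0; entries at or above the cutoff and all
#' diagonal entries are retained.  The thresholded matrix captures only the
#' closer relationships (families) and is fitted as a second random effect
#' to absorb family-environment resemblance.
#'
#' @param G symmetric relationship matrix.
#' @param cutoff off-diagonal threshold (default 0.05).
#' @return sparse symmetric \code{Matrix}.
#' @export
thresholdGrm <- function(G, cutoff = 0.05) {
  Gt <- G
  off <- Gt < cutoff
  diag(off) <- FALSE
  Gt[off] <- 0
  Matrix::Matrix(Gt, sparse = TRUE)
}

#' Build the GRM pair used by the two-variance-component model
#'
#' @inheritParams computeGrm
#' @param ids individual identifiers in row order of \code{dosages}.
#' @param cutoff threshold for the companion matrix, see
#'   \code{\link{thresholdGrm}}.
#' @return a \linkS4class{GrmPair}.
#' @export
grmPair <- function(dosages, ids = rownames(dosages), allele_freqs = NULL,
                    cutoff = 0.05) {
  G <- computeGrm(dosages, allele_freqs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  new("GrmPair", G = unname(G), Gt = thresholdGrm(unname(G), cutoff),
      ids = as.character(ids), cutoff = cutoff)
}

#' Alt-allele dosage matrix of a panel
#'
#' Sums the two haploid allele codes per individual at every SNP.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param maf_min SNPs with minor-allele frequency below this are dropped
#'   (set 0 to keep all).
#' @return numeric matrix, individuals x SNPs, entries 0/1/2; SNP columns
#'   meeting the MAF screen, named by SNP id.
#' @export
snpDosages <- function(panel, maf_min = 0.01) {
  H <- panelHaplotypes(panel)
  n <- nIndividuals(panel)
  i1 <- seq(1L, 2L * n, by = 2L)
  X <- H[i1, , drop = FALSE] + H[i1 + 1L, , drop = FALSE]
  dimnames(X) <- list(panelIndividuals(panel), panelSnps(panel)$id)
  if (maf_min > 0) {
    p <- colMeans(X) / 2
    X <- X[, pmin(p, 1 - p) >= maf_min, drop = FALSE]
  }
  X
}

#' Export a GRM as id-pair triplets
#'
#' Writes the lower triangle (including the diagonal) as
#' \code{id1 id2 value} text, a GCTA-compatible interchange layout.
#'
#' @param G relationship matrix with ids.
#' @param ids individual identifiers.
#' @param path output path.
#' @export
writeGrmTriplets <- function(G, ids, path) {
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                    value = formatC(G[idx], digits = 10, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
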