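#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom stats pchisq qchisq pnorm qnorm rnorm rbinom runif rpois median
#'   quantile var cor sd setNames complete.cases model.matrix
#' @importFrom utils read.table write.table
NULL

#' Phased haplotype panel
#'
#' Container for a fully phased diploid panel: an ordered SNP table with
#' physical (bp) and genetic-map (cM) coordinates, and one integer matrix of
#' haploid allele codes (0 = reference, 1 = alternate) with two rows per
#' individual.  Individual \code{i} owns rows \code{2*i - 1} and \code{2*i}.
#'
#' @slot snps data.frame with columns \code{id}, \code{chrom}, \code{bp},
#'   \code{cm}, \code{ref}, \code{alt}; within each chromosome \code{bp} is
#'   strictly increasing and \code{cm} non-decreasing.
#' @slot individuals character vector of sample identifiers.
#' @slot haplotypes integer matrix, \code{2 * length(individuals)} rows by
#'   \code{nrow(snps)} columns, entries in \{0, 1\}; no missing values
#'   (the panel is fully phased by contract).
#'
#' @export
setClass("PhasedPanel",
  representation(
    snps = "data.frame",
    individuals = "character",
    haplotypes = "matrix"
  )
)

setValidity("PhasedPanel", function(object) {
  msg <- character()
  sn <- object@snps
  need <- c("id", "chrom", "bp", "cm", "ref", "alt")
  if (!all(need %in% names(sn)))
    msg <- c(msg, paste("snps must have columns:", paste(need, collapse = ", ")))
  H <- object@haplotypes
  if (!is.integer(H) && !is.numeric(H))
    msg <- c(msg, "haplotypes must be a numeric/integer matrix")
  if (nrow(H) != 2L * length(object@individuals))
    msg <- c(msg, "haplotypes must have two rows per individual")
  if (ncol(H) != nrow(sn))
    msg <- c(msg, "haplotypes must have one column per SNP")
  if (anyNA(H))
    msg <- c(msg, "missing haploid calls are not allowed")
  if (length(H) && !all(H %in% c(0L, 1L)))
    msg <- c(msg, "haploid allele codes must be 0 or 1")
  if (all(need %in% names(sn)) && nrow(sn)) {
    for (ch in unique(sn$chrom)) {
      b <- sn$bp[sn$chrom == ch]
      m <- sn$cm[sn$chrom == ch]
      if (is.unsorted(b, strictly = TRUE))
        msg <- c(msg, sprintf("bp not strictly increasing on chromosome %s", ch))
      if (is.unsorted(m))
        msg <- c(msg, sprintf("cm not non-decreasing on chromosome %s", ch))
    }
    if (any(sn$bp < 1)) msg <- c(msg, "bp positions must be >= 1")
  }
  if (anyDuplicated(object@individuals))
    msg <- c(msg, "duplicate individual IDs")
  if (length(msg)) msg else TRUE
})

#' Construct a PhasedPanel
#'
#' @param snps SNP table (see \linkS4class{PhasedPanel}).
#' @param individuals character vector of sample IDs.
#' @param haplotypes integer matrix of haploid allele codes, two rows per
#'   individual in the order of \code{individuals}.
#' @return A \linkS4class{PhasedPanel}.
#' @examples
#' snps <- data.frame(id = c("s1", "s2"), chrom = "1", bp = c(100L, 200L),
#'                    cm = c(0, 0.01), ref = "A", alt = "G")
#' H <- rbind(c(0L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 1L))
#' PhasedPanel(snps, c("i1", "i2"), H)
#' @export
PhasedPanel <- function(snps, individuals, haplotypes) {
  storage.mode(haplotypes) <- "integer"
  snps$chrom <- as.character(snps$chrom)
  snps$bp <- as.integer(snps$bp)
  rownames(snps) <- NULL
  new("PhasedPanel", snps = snps, individuals = as.character(individuals),
      haplotypes = haplotypes)
}

#' @describeIn PhasedPanel-class number of individuals
#' @param object,x a \code{PhasedPanel}
#' @export
setMethod("length", "PhasedPanel", function(x) length(x@individuals))

#' Accessors for PhasedPanel
#'
#' \code{panelSnps}, \code{panelIndividuals} and \code{panelHaplotypes}
#' return the SNP table, the sample IDs and the haploid allele matrix;
#' \code{nSnps} and \code{nIndividuals} the respective counts.
#'
#' @param panel a \linkS4class{PhasedPanel}
#' @return the corresponding slot value (or count)
#' @export
panelSnps <- function(panel) panel@snps

#' @rdname panelSnps
#' @export
panelIndividuals <- function(panel) panel@individuals

#' @rdname panelSnps
#' @export
panelHaplotypes <- function(panel) panel@haplotypes

#' @rdname panelSnps
#' @export
nSnps <- function(panel) nrow(panel@snps)

#' @rdname panelSnps
#' @export
nIndividuals <- function(panel) length(panel@individuals)

setMethod("show", "PhasedPanel", function(object) {
  cat("PhasedPanel:", length(object@individuals), "individuals,",
      nrow(object@snps), "SNPs on",
      length(unique(object@snps$chrom)), "chromosome(s)\n")
})

#' Genomic relationship matrix pair
#'
#' Holds the SNP-based genomic relationship matrix G and its thresholded
#' companion Gt in which off-diagonal entries below a cutoff are zeroed.
#' Gt models only the closer relationships; fitting both matrices jointly
#' separates family resemblance from subtler structure.
#'
#' @slot G symmetric numeric matrix of genomic relationships.
#' @slot Gt sparse symmetric matrix; equal to G except off-diagonals below
#'   \code{cutoff} are 0.
#' @slot ids individual order shared by both matrices.
#' @slot cutoff the off-diagonal threshold applied to form Gt.
#' @export
setClass("GrmPair",
  representation(G = "matrix", Gt = "Matrix", ids = "character",
                 cutoff = "numeric")
)

setValidity("GrmPair", function(object) {
  msg <- character()
  G <- object@G
  if (nrow(G) != ncol(G)) msg <- c(msg, "G must be square")
  if (!isSymmetric(unname(G), tol = 1e-8)) msg <- c(msg, "G must be symmetric")
  if (length(object@ids) != nrow(G))
    msg <- c(msg, "ids length must match G dimension")
  Gt <- object@Gt
  if (!all(dim(Gt) == dim(G))) msg <- c(msg, "Gt must match G in dimension")
  if (nrow(G)) {
    if (max(abs(Matrix::diag(Gt) - diag(G))) > 1e-12)
      msg <- c(msg, "diag(Gt) must equal diag(G)")
    off <- Gt
    Matrix::diag(off) <- 0
    v <- off@x
    if (length(v) && any(v != 0 & v < object@cutoff))
      msg <- c(msg, "nonzero off-diagonals of Gt must be >= cutoff")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GrmPair", function(object) {
  n <- nrow(object@G)
  off <- object@Gt
  Matrix::diag(off) <- 0
  cat(sprintf("GrmPair: %d x %d; cutoff %.3g; %d retained off-diagonal pairs in Gt\n",
              n, n, object@cutoff, sum(off != 0) / 2L))
})

#' REML variance-component fit
#'
#' Result of restricted maximum likelihood estimation for the linear mixed
#' model with one or two genomic random effects and an i.i.d. residual.
#'
#' @slot sigma2 named vector of variance components (one per random term,
#'   last entry the residual), all non-negative.
#' @slot loglik restricted log-likelihood at convergence (constant terms
#'   dropped).
#' @slot converged logical; TRUE when the log-likelihood change fell below
#'   tolerance within the iteration budget.
#' @slot iterations iterations used.
#' @slot n number of records.
#' @export
setClass("RemlFit",
  representation(sigma2 = "numeric", loglik = "numeric",
                 converged = "logical", iterations = "integer", n = "integer")
)

setValidity("RemlFit", function(object) {
  if (any(object@sigma2 < -1e-12)) "variance components must be >= 0" else TRUE
})

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit (", if (object@converged) "converged" else "NOT converged",
      ", ", object@iterations, " iterations, n = ", object@n, ")\n", sep = "")
  print(signif(object@sigma2, 5))
  cat("restricted log-likelihood:", format(object@loglik), "\n")
})

#' @rdname RemlFit-class
#' @param fit a \linkS4class{RemlFit}
#' @return \code{varComponents} returns the named vector of variance
#'   components.
#' @export
varComponents <- function(fit) fit@sigma2
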