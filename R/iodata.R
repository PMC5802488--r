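#' Read a phased VCF into a PhasedPanel
#'
#' Parses a VCF whose GT fields are fully phased ("|" separator) diploid
#' hard calls at biallelic sites.  Anything else is a hard error: unphased
#' separators, missing calls and multi-allelic records all abort, because
#' downstream haplotype calling assumes two complete haploid sequences per
#' individual.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @return A \linkS4class{PhasedPanel}.  Genetic-map positions (\code{cm})
#'   are initialised to \code{NA} and are assigned with
#'   \code{\link{assignCm}}.
#' @seealso \code{\link{writePhasedVcf}} for the inverse operation.
#' @export
readPhasedVcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("non-biallelic record(s) in VCF; only biallelic SNPs are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  if (anyNA(gt) || any(gt == "." | gt == "./." | gt == ".|."))
    stop("missing genotype call(s); the panel must be fully phased")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype separator '/' found; input must be phased ('|')")
  if (!all(grepl("^[01]\\|[01]$", gt)))
    stop("malformed GT field(s); expected phased diploid calls like 0|1")
  ids <- colnames(gt)
  m <- nrow(gt); n <- ncol(gt)
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = m)
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = m)
  # interleave: individual i -> rows 2i-1, 2i; SNPs as columns
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  H[seq(1L, 2L * n, by = 2L), ] <- t(h1)
  H[seq(2L, 2L * n, by = 2L), ] <- t(h2)
  snps <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = as.character(fix[, "CHROM"]),
    bp = as.integer(fix[, "POS"]),
    cm = NA_real_,
    ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )
  for (ch in unique(snps$chrom)) {
    b <- snps$bp[snps$chrom == ch]
    if (is.unsorted(b, strictly = TRUE))
      stop("bp positions not strictly increasing on chromosome ", ch)
  }
  sn <- snps; sn$cm <- 0  # validity needs numeric cm; restore NA after
  p <- PhasedPanel(sn, ids, H)
  p@snps$cm <- NA_real_
  p
}

#' Write a PhasedPanel as a phased VCF
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param path output path (plain-text VCF 4.2).
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  sn <- panelSnps(panel)
  H <- panelHaplotypes(panel)
  n <- nIndividuals(panel)
  i1 <- seq(1L, 2L * n, by = 2L)
  gt <- matrix(paste0(t(H[i1, , drop = FALSE]), "|",
                      t(H[i1 + 1L, , drop = FALSE])), nrow = nrow(sn))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haploscan",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panelIndividuals(panel)), collapse = "\t"))
  body <- cbind(sn$chrom, sn$bp, sn$id, sn$ref, sn$alt, ".", ".", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recombination map
#'
#' Reads a genetic map in the four-column HapMap-style text layout
#' (Chromosome, Position(bp), Rate(cM/Mb), Map(cM)), with or without a
#' header line.  Within each chromosome bp must be strictly increasing and
#' the cumulative map non-decreasing.
#'
#' @param path path to the map file.
#' @return data.frame with columns \code{chrom}, \code{bp}, \code{rate},
#'   \code{cm}.
#' @export
readGeneticMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty genetic map file: ", path)
  has_header <- !grepl("^\\s*\\S+\\s+[0-9]+\\s", first)
  mp <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("genetic map must have 4 columns")
  mp <- mp[, 1:4]
  names(mp) <- c("chrom", "bp", "rate", "cm")
  mp$chrom <- as.character(mp$chrom)
  mp$bp <- as.integer(mp$bp)
  if (nrow(mp) == 0L) stop("empty genetic map file: ", path)
  for (ch in unique(mp$chrom)) {
    i <- mp$chrom == ch
    if (is.unsorted(mp$bp[i], strictly = TRUE))
      stop("non-monotone map: bp not strictly increasing on chromosome ", ch)
    if (is.unsorted(mp$cm[i]))
      stop("non-monotone map: cM decreasing on chromosome ", ch)
  }
  rownames(mp) <- NULL
  mp
}

#' @rdname readGeneticMap
#' @param map data.frame as returned by \code{readGeneticMap}.
#' @export
writeGeneticMap <- function(map, path) {
  out <- data.frame(Chromosome = map$chrom, `Position(bp)` = map$bp,
                    `Rate(cM/Mb)` = map$rate, `Map(cM)` = map$cm,
                    check.names = FALSE)
  write.table(format(out, digits = 12, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with named columns \code{iid}, \code{y}, \code{sex},
#' \code{age} and optional \code{batch} and \code{centre}.  The trait is
#' binary; anything outside \{0, 1\} is rejected, as are duplicate IDs.
#'
#' @param path path to the TSV.
#' @param panel optional \linkS4class{PhasedPanel}; when given, every
#'   phenotyped ID must be present in the panel.
#' @return data.frame of phenotypes and covariates.
#' @export
readPhenotypes <- function(path, panel = NULL) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("iid", "y", "sex", "age")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (!all(ph$y %in% c(0, 1)))
    stop("trait values outside {0,1}; y must be binary")
  if (anyDuplicated(ph$iid)) stop("duplicate iid in phenotype table")
  if (!is.null(panel) && !all(ph$iid %in% panelIndividuals(panel)))
    stop("phenotype table contains IDs absent from the panel")
  ph
}

#' @rdname readPhenotypes
#' @param pheno data.frame of phenotypes.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SUMMARY_COLS <- c("chrom", "start_bp", "end_bp", "window_cm", "allele_string",
                   "freq", "hwe_x2", "beta", "se", "p", "or_", "or_lo", "or_hi")

#' Write / read association summary statistics
#'
#' One row per tested haplotype allele.  Numeric columns are written at 12
#' significant digits so a write/read cycle is lossless at that precision.
#'
#' @param results data.frame containing at least the summary columns
#'   \code{chrom, start_bp, end_bp, window_cm, allele_string, freq, hwe_x2,
#'   beta, se, p, or_, or_lo, or_hi}.
#' @param path output path.
#' @return \code{path} (writer) or the results data.frame (reader).
#' @export
writeSummaryStats <- function(results, path) {
  miss <- setdiff(.SUMMARY_COLS, names(results))
  if (length(miss))
    stop("results missing columns: ", paste(miss, collapse = ", "))
  out <- results[, union(.SUMMARY_COLS, names(results))]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  res <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(allele_string = "character"),
                    stringsAsFactors = FALSE)
  miss <- setdiff(.SUMMARY_COLS, names(res))
  if (length(miss))
    stop("summary file missing columns: ", paste(miss, collapse = ", "))
  res
}
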