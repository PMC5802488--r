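#' Interpolate genetic-map position
#'
#' Piecewise-linear interpolation of the cumulative Map(cM) column of a
#' recombination map at arbitrary base-pair positions.  Queries outside the
#' mapped interval are clamped to the boundary cM (no extrapolation beyond
#' the map ends).
#'
#' @param map data.frame from \code{\link{readGeneticMap}}.
#' @param chrom chromosome identifier.
#' @param bp numeric vector of base-pair positions.
#' @return numeric vector of cM positions, non-decreasing in \code{bp}.
#' @export
interpolateCm <- function(map, chrom, bp) {
  i <- map$chrom == as.character(chrom)
  if (!any(i)) stop("unknown chromosome in map: ", chrom)
  x <- map$bp[i]; y <- map$cm[i]
  if (length(x) == 1L) return(rep(y, length(bp)))
  stats::approx(x, y, xout = pmin(pmax(bp, x[1]), x[length(x)]),
                method = "linear", ties = "ordered")$y
}

#' Assign cM coordinates to panel SNPs
#'
#' Interpolates the genetic map once per chromosome and caches the result
#' in the panel's SNP table.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param map genetic map data.frame.
#' @return the panel with \code{snps$cm} filled in.
#' @export
assignCm <- function(panel, map) {
  sn <- panelSnps(panel)
  for (ch in unique(sn$chrom)) {
    i <- sn$chrom == ch
    sn$cm[i] <- interpolateCm(map, ch, sn$bp[i])
  }
  panel@snps <- sn
  validObject(panel)
  panel
}

#' Tile sliding cM windows over a SNP table
#'
#' Windows of a fixed genetic length are anchored at the cM position of the
#' first SNP of each chromosome and advanced by a fixed fraction of the
#' window size (default one quarter) while the anchor lies before the last
#' SNP.  A window collects the SNPs whose cM position falls in the half-open
#' interval [anchor, anchor + size); windows holding fewer than
#' \code{min_snps} SNPs are dropped.
#'
#' @param snps SNP table with \code{chrom}, \code{bp}, \code{cm} assigned.
#' @param size_cm window genetic length in cM (typically 1, 0.5 or 0.25).
#' @param step_fraction anchor advance as a fraction of \code{size_cm}.
#' @param min_snps minimum SNP count for a window to be kept.
#' @return data.frame of windows: \code{chrom}, \code{size_cm},
#'   \code{first_idx}, \code{last_idx} (inclusive indices into the SNP
#'   table), \code{start_bp}, \code{end_bp} (outermost SNPs), \code{start_cm}
#'   (the anchor) and \code{n_snps}; ordered by chromosome then anchor.
#' @export
tileWindows <- function(snps, size_cm, step_fraction = 0.25, min_snps = 5L) {
  if (nrow(snps) == 0L) stop("empty SNP table")
  if (anyNA(snps$cm)) stop("cm coordinates not assigned; run assignCm first")
  step <- size_cm * step_fraction
  out <- vector("list", 0L)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    cm <- snps$cm[idx]
    anchor <- cm[1]
    last_cm <- cm[length(cm)]
    k <- 0L
    while (TRUE) {
      a <- anchor + k * step
      if (a >= last_cm && k > 0L) break
      inw <- idx[cm >= a & cm < a + size_cm]
      if (length(inw) >= min_snps) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, size_cm = size_cm,
          first_idx = inw[1], last_idx = inw[length(inw)],
          start_bp = snps$bp[inw[1]], end_bp = snps$bp[inw[length(inw)]],
          start_cm = a, n_snps = length(inw),
          stringsAsFactors = FALSE)
      }
      k <- k + 1L
      if (a >= last_cm) break
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), size_cm = numeric(),
                      first_idx = integer(), last_idx = integer(),
                      start_bp = integer(), end_bp = integer(),
                      start_cm = numeric(), n_snps = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export windows in BED-like form
#'
#' Writes chrom, 0-based half-open start, end and window size -- the usual
#' BED convention, applied here only for export; all internal coordinates
#' are 1-based inclusive.
#'
#' @param windows window table from \code{\link{tileWindows}}.
#' @param path output path.
#' @export
writeWindowsBed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom, start = windows$start_bp - 1L,
                    end = windows$end_bp, size_cm = windows$size_cm)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
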