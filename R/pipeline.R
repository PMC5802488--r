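#' Pipeline run configuration
#'
#' Validates the knobs of \code{\link{runPipeline}} before any compute.
#'
#' @param vcf,map,pheno input paths (phased VCF, recombination map,
#'   phenotype TSV), or \code{NULL} when in-memory objects are passed to
#'   \code{runPipeline} directly.
#' @param window_sizes cM window sizes, a subset of \{1, 0.5, 0.25\}.
#' @param p_min,p_max,x2_max haplotype QC thresholds (see
#'   \code{\link{qcFilter}}).
#' @param two_grm fit G and its thresholded companion (family cohort) or
#'   G alone.
#' @param grm_cutoff off-diagonal threshold for the companion GRM.
#' @param covariates fixed-effect covariates (see
#'   \code{\link{designMatrix}}).
#' @param candidate_p discovery threshold below which haplotypes are
#'   carried to replication (default 1e-6).
#' @param finemap_p fine-mapping candidate threshold (default 1e-3).
#' @param genomewide_p genome-wide significance flag level (default 5e-8).
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param maf_min MAF screen for SNPs entering the GRM.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return validated config list of class \code{haploscan_runconfig}.
#' @export
runConfig <- function(vcf = NULL, map = NULL, pheno = NULL,
                      window_sizes = c(1, 0.5, 0.25),
                      p_min = 0.005, p_max = 0.995, x2_max = 24,
                      two_grm = TRUE, grm_cutoff = 0.05,
                      covariates = c("sex", "age", "age2"),
                      candidate_p = 1e-6, finemap_p = 1e-3,
                      genomewide_p = 5e-8, clump_r2 = 0.4, clump_kb = 1000,
                      maf_min = 0.01, seed = 1L, out_dir = tempfile("haploscan_")) {
  if (!length(window_sizes) || !all(window_sizes %in% c(1, 0.5, 0.25)))
    stop("window_sizes must be a non-empty subset of {1, 0.5, 0.25}")
  for (v in c(p_min, p_max, candidate_p, finemap_p, genomewide_p))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0,1)")
  if (p_min >= p_max) stop("p_min must be below p_max")
  if (clump_r2 <= 0 || clump_r2 > 1) stop("clump_r2 must be in (0,1]")
  structure(list(vcf = vcf, map = map, pheno = pheno,
                 window_sizes = window_sizes, p_min = p_min, p_max = p_max,
                 x2_max = x2_max, two_grm = two_grm, grm_cutoff = grm_cutoff,
                 covariates = covariates, candidate_p = candidate_p,
                 finemap_p = finemap_p, genomewide_p = genomewide_p,
                 clump_r2 = clump_r2, clump_kb = clump_kb, maf_min = maf_min,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "haploscan_runconfig")
}

.stage <- function(name, expr, manifest_env) {
  tryCatch(expr, error = function(e) {
    manifest_env$manifest$failed_stage <- name
    manifest_env$manifest$error <- conditionMessage(e)
    manifest_env$manifest$complete <- FALSE
    .write_manifest(manifest_env)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_manifest <- function(env) {
  jsonlite::write_json(env$manifest,
                       file.path(env$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the discovery -> fine-map -> clump (-> replication -> meta) workflow
#'
#' Executes the full haplotype association pipeline: window tiling per size
#' class, haplotype calling and QC, GRM construction, null-model REML,
#' the mixed-model scan, fine mapping of overlapping hits, LD clumping
#' with Bonferroni bookkeeping, and -- when a replication cohort is given --
#' a single-GRM replication scan of discovery candidates followed by
#' fixed-effect inverse-variance meta-analysis.  All tables are written as
#' TSV into \code{config$out_dir} together with a MANIFEST recording seed,
#' filter counts and completion state.
#'
#' @param config a \code{\link{runConfig}}.
#' @param discovery optional list \code{(panel, pheno, map)} of in-memory
#'   inputs (e.g. from \code{\link{simulateCohort}}); when absent the paths
#'   in \code{config} are read.
#' @param replication optional list \code{(panel, pheno)} for a replication
#'   cohort on the same SNPs and allele orientation; its covariates may
#'   additionally include \code{batch}/\code{centre} columns present in its
#'   phenotype table.
#' @return (invisibly) a list with the scan, fine-mapping, clump, and
#'   meta-analysis results plus the output directory.
#' @export
runPipeline <- function(config, discovery = NULL, replication = NULL) {
  stopifnot(inherits(config, "haploscan_runconfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$out_dir <- out_dir
  env$manifest <- list(package = "haploscan",
                       version = as.character(utils::packageVersion("haploscan")),
                       seed = config$seed, complete = FALSE, counts = list())
  .write_manifest(env)

  if (is.null(discovery)) {
    discovery <- .stage("read-inputs", {
      panel <- readPhasedVcf(config$vcf)
      mp <- readGeneticMap(config$map)
      ph <- readPhenotypes(config$pheno, panel)
      list(panel = assignCm(panel, mp), pheno = ph, map = mp)
    }, env)
  } else if (anyNA(panelSnps(discovery$panel)$cm)) {
    discovery$panel <- assignCm(discovery$panel, discovery$map)
  }
  panel <- discovery$panel

  windows <- .stage("tile-windows", {
    do.call(rbind, lapply(config$window_sizes, function(s)
      tileWindows(panelSnps(panel), s)))
  }, env)
  if (!nrow(windows)) stop("no windows of at least 5 SNPs; map too sparse")
  env$manifest$counts$windows_kept <- nrow(windows)
  env$manifest$counts$windows_per_size <-
    as.list(table(windows$size_cm))

  catalogue <- .stage("haplotype-qc", {
    catalogueHaplotypes(panel, windows, p_min = config$p_min,
                        p_max = config$p_max, x2_max = config$x2_max)
  }, env)
  env$manifest$counts$alleles_total <- nrow(catalogue)
  env$manifest$counts$alleles_kept <- sum(!catalogue$merged)
  env$manifest$counts$alleles_merged <- sum(catalogue$merged)

  grm <- .stage("grm", {
    grmPair(snpDosages(panel, config$maf_min),
            ids = panelIndividuals(panel), cutoff = config$grm_cutoff)
  }, env)

  scan <- .stage("mlm-scan", {
    scanHaplotypes(panel, catalogue, discovery$pheno, grm,
                   two_grm = config$two_grm, covariates = config$covariates)
  }, env)
  env$manifest$counts$alleles_tested <- nrow(scan$results)
  env$manifest$lambda_gc <- scan$lambda_gc
  env$manifest$case_fraction <- scan$case_fraction
  env$manifest$varcomp <- as.list(varComponents(scan$fit))
  writeSummaryStats(scan$results, file.path(out_dir, "discovery_scan.tsv"))

  fm <- .stage("fine-map", {
    fineMap(panel, scan, p_thresh = config$finemap_p)
  }, env)
  env$manifest$counts$refined_haplotypes <- nrow(fm)
  if (nrow(fm))
    writeSummaryStats(fm, file.path(out_dir, "finemap.tsv"))

  clumps <- .stage("clump", {
    res <- scan$results
    dos <- haplotypeDosages(panel, res)
    clumpResults(res, dos, config$clump_r2, config$clump_kb)
  }, env)
  env$manifest$counts$independent_haplotypes <- clumps$n_independent
  env$manifest$bonferroni_alpha <- clumps$bonferroni_alpha
  ct <- scan$results
  ct$clump <- clumps$assignment
  ct$genomewide <- ct$p < config$genomewide_p
  write.table(ct[, c("chrom", "start_bp", "end_bp", "window_cm",
                     "allele_string", "p", "clump", "genomewide")],
              file.path(out_dir, "clumps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  meta <- NULL
  rep_scan <- NULL
  if (!is.null(replication)) {
    rep_scan <- .stage("replication-scan", {
      cand <- scan$results[scan$results$p < config$candidate_p, , drop = FALSE]
      if (!nrow(cand)) return(NULL)
      rp <- replication$panel
      if (anyNA(panelSnps(rp)$cm)) rp <- assignCm(rp, discovery$map)
      rcov <- intersect(c(config$covariates, "batch", "centre"),
                        c(names(replication$pheno), "age2"))
      rgrm <- computeGrm(snpDosages(rp, config$maf_min))
      # re-derive allele frequency and HWE in the replication cohort
      rcat <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
        d <- haplotypeDosage(rp, cand[i, ], cand$allele_string[i])
        cnt <- tabulate(d + 1L, 3L)  # aa, Aa, AA
        data.frame(window_id = cand$window_id[i], chrom = cand$chrom[i],
                   size_cm = cand$window_cm[i],
                   first_idx = cand$first_idx[i],
                   last_idx = cand$last_idx[i],
                   start_bp = cand$start_bp[i], end_bp = cand$end_bp[i],
                   allele_string = cand$allele_string[i],
                   obs_AA = cnt[3], obs_Aa = cnt[2], obs_aa = cnt[1],
                   n = length(d),
                   p = haplotypeFrequency(cnt[3], cnt[2], cnt[1]),
                   q = 1 - haplotypeFrequency(cnt[3], cnt[2], cnt[1]),
                   x2 = hweChisq(cnt[3], cnt[2], cnt[1]),
                   merged = FALSE, stringsAsFactors = FALSE)
      }))
      out <- scanHaplotypes(rp, rcat, replication$pheno, rgrm,
                            two_grm = FALSE, covariates = rcov)
      out$candidates <- cand
      out
    }, env)
    if (!is.null(rep_scan) && nrow(rep_scan$results)) {
      writeSummaryStats(rep_scan$results,
                        file.path(out_dir, "replication_scan.tsv"))
      meta <- .stage("meta-analysis", {
        key <- c("window_id", "allele_string")
        disc <- rep_scan$candidates
        repl <- rep_scan$results
        mk <- merge(disc, repl, by = key, suffixes = c("_disc", "_rep"))
        if (!nrow(mk)) return(NULL)
        rows <- lapply(seq_len(nrow(mk)), function(i) {
          # meta-analyse on the log-OR scale
          d <- orCiToBetaSe(mk$or__disc[i], mk$or_lo_disc[i], mk$or_hi_disc[i])
          r <- orCiToBetaSe(mk$or__rep[i], mk$or_lo_rep[i], mk$or_hi_rep[i])
          mm <- ivwMeta(c(d["beta"], r["beta"]), c(d["se"], r["se"]))
          data.frame(window_id = mk$window_id[i],
                     allele_string = mk$allele_string[i],
                     chrom = mk$chrom_disc[i], start_bp = mk$start_bp_disc[i],
                     end_bp = mk$end_bp_disc[i],
                     p_disc = mk$p_disc[i], p_rep = mk$p_rep[i],
                     beta_meta = mm$beta, se_meta = mm$se, p_meta = mm$p,
                     or_meta = mm$or_, or_lo_meta = mm$or_lo,
                     or_hi_meta = mm$or_hi, stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
      }, env)
      if (!is.null(meta))
        write.table(meta, file.path(out_dir, "meta_analysis.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  env$manifest$complete <- TRUE
  .write_manifest(env)
  invisible(list(scan = scan, finemap = fm, clumps = clumps,
                 replication = rep_scan, meta = meta,
                 manifest = env$manifest, out_dir = out_dir))
}
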