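#' Bundled two-cohort candidate haplotype summary statistics
#'
#' Published-style summary rows for twelve candidate risk haplotypes for
#' major depressive disorder from a two-cohort haplotype GWAS: odds ratio
#' with 95\% CI and P-value in a family-based discovery cohort (P < 1e-6
#' haplotypes, clinically ascertained MDD, prevalence 13.9\%) and in a
#' population-based replication cohort (questionnaire-ascertained,
#' prevalence 34.0\%, 8,508 cases / 16,527 controls), plus the haplotype
#' frequency observed in each cohort.  Used as worked-example input for
#' \code{\link{ivwMeta}}, \code{\link{orCiToBetaSe}} and
#' \code{\link{allelicPower}}.
#'
#' @return data.frame with columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{window_cm}, \code{or_disc}, \code{or_lo_disc},
#'   \code{or_hi_disc}, \code{p_disc}, \code{or_rep}, \code{or_lo_rep},
#'   \code{or_hi_rep}, \code{p_rep}, \code{freq_disc}, \code{freq_rep}.
#' @examples
#' cand <- candidateHaplotypes()
#' # analytic power to replicate each candidate at alpha = 0.05
#' allelicPower(grr = cand$or_disc, freq = cand$freq_rep, K = 0.146,
#'              n_case = 8508, n_control = 16527)
#' @export
candidateHaplotypes <- function() {
  path <- system.file("extdata", "discovery_candidates.tsv",
                      package = "haploscan", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
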