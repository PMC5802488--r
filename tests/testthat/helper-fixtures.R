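# Shared fixtures: tiny deterministic panels and a cached simulated cohort.

# 4 individuals x 6 SNPs, hand-written haploids
toy_panel <- function() {
  snps <- data.frame(id = paste0("s", 1:6), chrom = "1",
                     bp = c(100L, 200L, 300L, 400L, 500L, 600L),
                     cm = seq(0, 0.5, by = 0.1), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  H <- rbind(
    c(0, 1, 0, 1, 0, 1),  # ind1 hap1
    c(0, 1, 0, 1, 0, 1),  # ind1 hap2
    c(0, 1, 0, 0, 1, 1),  # ind2 hap1
    c(1, 1, 0, 1, 0, 1),  # ind2 hap2
    c(0, 0, 0, 1, 0, 1),  # ind3 hap1
    c(0, 1, 0, 1, 0, 1),  # ind3 hap2
    c(1, 0, 1, 0, 1, 0),  # ind4 hap1
    c(1, 0, 1, 0, 1, 0))  # ind4 hap2
  PhasedPanel(snps, paste0("ind", 1:4), H)
}

# evenly spaced map: n points, step_cm apart, 1000 bp apart
even_map <- function(n = 11, step_cm = 0.1, chrom = "1") {
  data.frame(chrom = chrom, bp = seq(1000L, by = 1000L, length.out = n),
             rate = step_cm * 1000, cm = seq(0, by = step_cm, length.out = n),
             stringsAsFactors = FALSE)
}

# one small family-structured cohort reused across files
small_sim_cache <- new.env()
small_sim <- function() {
  if (is.null(small_sim_cache$sim)) {
    small_sim_cache$sim <- simulateCohort(simConfig(
      n_individuals = 200L, n_snps = 300L, map_length_cm = 3,
      seed = 101L))
  }
  small_sim_cache$sim
}

# window table over a panel, one size class
windows_for <- function(panel, size_cm = 0.25) {
  tileWindows(panelSnps(panel), size_cm)
}

# random genotype-class counts for HWE oracle checks
random_counts <- function(n_trip, seed) {
  set.seed(seed)
  t(vapply(seq_len(n_trip), function(i) {
    n <- sample(20:500, 1)
    p <- runif(1, 0.02, 0.98)
    as.integer(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
  }, integer(3)))
}
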