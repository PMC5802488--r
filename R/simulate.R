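#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort
#' generator.  Defaults emulate a family-structured discovery cohort:
#' a singleton-heavy family-size distribution with families up to 31
#' members, SNPs at roughly uniform genetic density with alt-allele
#' frequencies above 1\% minor-allele frequency, blocky founder LD from a
#' first-order Markov haplotype chain, and a binary trait of prevalence
#' 13.9\% from a liability-threshold model with sex/age covariate effects
#' and a pedigree-correlated polygenic term.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of biallelic SNPs on the (single) chromosome.
#' @param chrom chromosome label.
#' @param map_length_cm genetic length of the simulated region.
#' @param rate_sd lognormal sd of the per-segment recombination rate around
#'   1 cM/Mb (0 gives a uniform map).
#' @param founder_ld adjacent-SNP copying probability of the founder
#'   haplotype Markov chain (0 = linkage equilibrium, near 1 = long
#'   haplotype blocks).
#' @param maf_range range of minor-allele frequencies for founder SNPs.
#' @param prevalence trait prevalence K; 0.139 mirrors a clinically
#'   ascertained discovery cohort, 0.340 a questionnaire-based replication
#'   cohort.
#' @param h2 liability-scale polygenic heritability.
#' @param b_sex,b_age,b_age2 liability covariate effects (age standardized
#'   internally); small nonzero defaults so covariate adjustment is
#'   exercised.
#' @param family_sizes,family_probs family-size support and probabilities;
#'   the default mirrors a cohort with many singletons, abundant small
#'   families and a thin tail to 31 members.
#' @param causal list of planted causal haplotypes, each a list with
#'   \code{locus} (central SNP index), \code{target_freq}, \code{beta}
#'   (liability scale, per copy) and optional \code{n_snps} (span,
#'   default 8) and \code{allele_string} (plant this exact allele rather
#'   than selecting the closest observed one -- used to share a causal
#'   allele across cohorts).
#' @param seed mandatory integer seed; every stage of the generator is a
#'   deterministic function of it.
#' @param map_seed optional separate seed for the map and the SNP allele
#'   frequencies; two cohorts simulated with the same \code{map_seed} but
#'   different \code{seed}s share their SNP panel (positions, cM, ref/alt
#'   frequencies), as a discovery/replication pair must.
#' @return validated config list of class \code{haploscan_simconfig}.
#' @export
simConfig <- function(n_individuals = 1000L, n_snps = 2000L, chrom = "1",
                      map_length_cm = 20, rate_sd = 0.3, founder_ld = 0.9,
                      maf_range = c(0.01, 0.5), prevalence = 0.139,
                      h2 = 0.3, b_sex = 0.1, b_age = 0.1, b_age2 = 0.05,
                      family_sizes = NULL, family_probs = NULL,
                      causal = list(), seed, map_seed = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(map_seed)) map_seed <- seed
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0,1)")
  if (founder_ld < 0 || founder_ld >= 1) stop("founder_ld must be in [0,1)")
  if (is.null(family_sizes)) {
    # singleton-heavy, thin tail to 31 (counts shaped like a family cohort)
    family_sizes <- c(1:4, 5:31)
    family_probs <- c(1789, 1799, 1216, 829, 1089 * 0.35 * 0.65^(0:26))
  }
  family_probs <- family_probs / sum(family_probs)
  for (cs in causal) {
    if (is.null(cs$locus) || is.null(cs$target_freq) || is.null(cs$beta))
      stop("each causal entry needs locus, target_freq and beta")
    if (cs$target_freq <= 0.005 - 1e-12 || cs$target_freq >= 0.5)
      stop("causal target_freq must be in (0.005, 0.5)")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), chrom = as.character(chrom),
                 map_length_cm = map_length_cm, rate_sd = rate_sd,
                 founder_ld = founder_ld, maf_range = maf_range,
                 prevalence = prevalence, h2 = h2, b_sex = b_sex,
                 b_age = b_age, b_age2 = b_age2,
                 family_sizes = family_sizes, family_probs = family_probs,
                 causal = causal, seed = as.integer(seed),
                 map_seed = as.integer(map_seed)),
            class = "haploscan_simconfig")
}

# stage-scoped seeds: independent reproducible substreams below 2^31
.stage_seed <- function(seed, stage) {
  (seed * 48271 + stage * 9973) %% 2147483647L
}

.sim_map <- function(config) {
  set.seed(.stage_seed(config$map_seed, 1L))
  m <- config$n_snps
  n_seg <- max(2L, m %/% 50L)
  # physical positions: jittered-uniform, strictly increasing
  gaps <- runif(m, 0.25, 1.75)
  span_bp <- config$map_length_cm * 1e6  # ~1 cM/Mb overall
  bp <- as.integer(round(cumsum(gaps) / sum(gaps) * (span_bp - m))) +
    seq_len(m)  # enforce strict increase
  seg_end <- unique(c(bp[round(seq(1, m, length.out = n_seg + 1L))[-1]]))
  rate <- exp(rnorm(length(seg_end), -config$rate_sd^2 / 2, config$rate_sd))
  # cumulative cM over segment boundaries, scaled to map_length_cm
  seg_start <- c(bp[1], seg_end[-length(seg_end)])
  dcm <- rate * (seg_end - seg_start) / 1e6
  cm <- c(0, cumsum(dcm)) * (config$map_length_cm / sum(dcm))
  pts_bp <- c(bp[1], seg_end)
  rate_scaled <- c(rate * (config$map_length_cm / sum(dcm)), 0)
  data.frame(chrom = config$chrom, bp = pts_bp, rate = rate_scaled,
             cm = cm, stringsAsFactors = FALSE)[!duplicated(pts_bp), ] -> mp
  rownames(mp) <- NULL
  attr(mp, "snp_bp") <- bp
  mp
}

.sim_founder_haplotypes <- function(config, n_haplos, freqs) {
  m <- config$n_snps
  H <- matrix(0L, n_haplos, m)
  U <- matrix(runif(n_haplos * m), n_haplos, m)
  copy <- matrix(runif(n_haplos * m) < config$founder_ld, n_haplos, m)
  u <- U[, 1]
  H[, 1] <- as.integer(u < freqs[1])
  for (j in 2:m) {
    fresh <- !copy[, j]
    u[fresh] <- U[fresh, j]
    H[, j] <- as.integer(u < freqs[j])
  }
  H
}

.sim_pedigree <- function(config) {
  set.seed(.stage_seed(config$seed, 2L))
  n <- config$n_individuals
  sizes <- integer(0)
  support <- config$family_sizes
  while (sum(sizes) < n) {
    pick <- sample.int(length(support), 64L, replace = TRUE,
                       prob = config$family_probs)
    sizes <- c(sizes, support[pick])
  }
  k <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0L]
  ped <- data.frame(iid = character(n), family = integer(n),
                    father = NA_integer_, mother = NA_integer_,
                    founder = FALSE, stringsAsFactors = FALSE)
  row <- 0L
  for (f in seq_along(sizes)) {
    sz <- sizes[f]
    members <- row + seq_len(sz)
    if (sz == 1L) {
      ped$founder[members] <- TRUE
    } else if (sz == 2L) {
      # parent-offspring pair: second member is child of the first and an
      # unobserved spouse (coded as mother = -1: spouse drawn at meiosis)
      ped$founder[members[1]] <- TRUE
      ped$father[members[2]] <- members[1]
      ped$mother[members[2]] <- -1L
    } else {
      ped$founder[members[1:2]] <- TRUE
      for (i in members[-(1:2)]) {
        if (i > members[3] && runif(1) < 0.35) {
          # third generation: child of a random earlier non-founder member
          # and an unobserved spouse
          cand <- setdiff(members[members < i], members[1:2])
          par <- cand[sample.int(length(cand), 1L)]
          ped$father[i] <- par
          ped$mother[i] <- -1L
        } else {
          ped$father[i] <- members[1]
          ped$mother[i] <- members[2]
        }
      }
    }
    ped$family[members] <- f
    row <- row + sz
  }
  ped$iid <- sprintf("ind%05d", seq_len(n))
  ped
}

.meiosis <- function(h1, h2, cm, n_cross, cross_pos, start) {
  # gamete as a crossover mosaic of the two parental haploids
  if (n_cross == 0L) return(if (start == 1L) h1 else h2)
  cuts <- sort(cross_pos)
  phase <- start + findInterval(cm, cuts)
  ifelse(phase %% 2L == 1L, h1, h2)
}

.gamete <- function(H, rows, cm, L_morgan) {
  n_cross <- rpois(1L, L_morgan)
  cross_pos <- runif(n_cross, min(cm), max(cm))
  start <- sample(1:2, 1L)
  .meiosis(H[rows[1], ], H[rows[2], ], cm, n_cross, cross_pos, start)
}

#' Simulate a family-structured phased cohort
#'
#' Generates, from a single seed: a recombination map; founder haplotypes
#' from a first-order Markov chain (blocky LD); a pedigree drawn from the
#' configured family-size distribution with offspring haploids formed by
#' meiosis (crossovers as a Poisson process on the cM map); optional
#' planted causal haplotype alleles; and a binary phenotype from a
#' liability-threshold model with covariate effects, a pedigree-correlated
#' polygenic term and unit-scale residual noise.  An individual is a case
#' when its liability exceeds the empirical (1 - K) quantile.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{panel} (\linkS4class{PhasedPanel}, cm assigned),
#'   \code{pheno} (phenotype table), \code{map} (genetic map data.frame)
#'   and \code{truth} (ledger of planted alleles, realized frequencies and
#'   dosages, variance components, realized prevalence, pedigree).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "haploscan_simconfig"))
  mp <- .sim_map(config)
  bp <- attr(mp, "snp_bp")
  m <- config$n_snps
  cm <- interpolateCm(mp, config$chrom, bp)
  ped <- .sim_pedigree(config)
  n <- nrow(ped)

  set.seed(.stage_seed(config$map_seed, 3L))
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  freqs <- ifelse(runif(m) < 0.5, maf, 1 - maf)  # alt-allele frequency
  set.seed(.stage_seed(config$seed, 6L))
  n_founder <- sum(ped$founder)
  n_spouse <- sum(ped$mother == -1L, na.rm = TRUE)
  FH <- .sim_founder_haplotypes(config, 2L * (n_founder + n_spouse), freqs)

  truth_causal <- list()
  for (ci in seq_along(config$causal)) {
    cs <- config$causal[[ci]]
    span <- if (!is.null(cs$allele_string)) nchar(cs$allele_string)
            else if (is.null(cs$n_snps)) 8L else as.integer(cs$n_snps)
    pl <- .plant_in_pool(FH, cs$locus, cs$target_freq, span,
                         allele = cs$allele_string)
    FH <- pl$pool
    truth_causal[[ci]] <- data.frame(
      first_idx = pl$first_idx, last_idx = pl$last_idx,
      allele_string = pl$allele_string, target_freq = cs$target_freq,
      founder_freq = pl$realized_freq, beta = cs$beta,
      edited_haploids = pl$edited, stringsAsFactors = FALSE)
  }

  # drop founder haplotypes through the pedigree
  set.seed(.stage_seed(config$seed, 4L))
  L_morgan <- config$map_length_cm / 100
  H <- matrix(0L, 2L * n, m)
  fidx <- 0L
  sidx <- 2L * n_founder
  for (i in seq_len(n)) {
    r <- c(2L * i - 1L, 2L * i)
    if (ped$founder[i]) {
      H[r[1], ] <- FH[fidx + 1L, ]
      H[r[2], ] <- FH[fidx + 2L, ]
      fidx <- fidx + 2L
    } else {
      fa <- ped$father[i]
      H[r[1], ] <- .gamete(H, c(2L * fa - 1L, 2L * fa), cm, L_morgan)
      if (ped$mother[i] == -1L) {
        H[r[2], ] <- .gamete(FH, c(sidx + 1L, sidx + 2L), cm, L_morgan)
        sidx <- sidx + 2L
      } else {
        mo <- ped$mother[i]
        H[r[2], ] <- .gamete(H, c(2L * mo - 1L, 2L * mo), cm, L_morgan)
      }
    }
  }

  snps <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                     chrom = config$chrom, bp = bp, cm = cm,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- PhasedPanel(snps, ped$iid, H)

  # liability-threshold phenotype
  set.seed(.stage_seed(config$seed, 5L))
  sex <- rbinom(n, 1L, 0.5)
  age <- runif(n, 18, 99)
  age_s <- (age - 58.5) / 23.4
  g <- numeric(n)
  sdg <- sqrt(config$h2)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      g[i] <- rnorm(1, 0, sdg)
    } else {
      gm <- if (ped$mother[i] == -1L) rnorm(1, 0, sdg) else g[ped$mother[i]]
      g[i] <- 0.5 * (g[ped$father[i]] + gm) + rnorm(1, 0, sdg / sqrt(2))
    }
  }
  e <- rnorm(n, 0, sqrt(1 - config$h2))
  liab <- config$b_sex * sex + config$b_age * age_s +
    config$b_age2 * age_s^2 + g + e
  causal_dos <- list()
  if (length(truth_causal)) {
    for (ci in seq_along(truth_causal)) {
      tc <- truth_causal[[ci]]
      win <- list(first_idx = tc$first_idx, last_idx = tc$last_idx)
      d <- haplotypeDosage(panel, win, tc$allele_string)
      causal_dos[[ci]] <- d
      truth_causal[[ci]]$realized_freq <- sum(d) / (2 * n)
      liab <- liab + tc$beta * d
    }
  }
  thr <- quantile(liab, 1 - config$prevalence, names = FALSE)
  y <- as.integer(liab > thr)

  pheno <- data.frame(iid = ped$iid, y = y, sex = sex, age = round(age, 1),
                      stringsAsFactors = FALSE)
  truth <- list(
    causal = if (length(truth_causal)) do.call(rbind, truth_causal) else NULL,
    causal_dosages = causal_dos,
    prevalence_target = config$prevalence, prevalence_realized = mean(y),
    h2 = config$h2, liability_threshold = thr,
    var_liability = var(liab),
    covariate_betas = c(sex = config$b_sex, age = config$b_age,
                        age2 = config$b_age2),
    pedigree = ped, seed = config$seed)
  list(panel = panel, pheno = pheno, map = mp[, c("chrom", "bp", "rate", "cm")],
       truth = truth)
}

# select (or minimally edit founders to create) an allele at target frequency
.plant_in_pool <- function(pool, locus, target_freq, span, allele = NULL) {
  m <- ncol(pool)
  first <- max(1L, min(locus - span %/% 2L, m - span + 1L))
  last <- first + span - 1L
  s <- do.call(paste0, as.data.frame(pool[, first:last, drop = FALSE]))
  if (is.null(allele)) {
    tab <- sort(table(s), decreasing = TRUE)
    fr <- as.numeric(tab) / length(s)
    rel <- abs(fr - target_freq) / target_freq
    best <- which.min(rel)
    allele <- names(tab)[best]
    off_target <- rel[best] > 0.25
  } else {
    stopifnot(nchar(allele) == span)
    tab <- setNames(sum(s == allele), allele)
    best <- 1L
    off_target <- abs(tab[[1]] / length(s) - target_freq) / target_freq > 0.25
  }
  edited <- 0L
  if (off_target) {
    want <- max(1L, round(target_freq * length(s)))
    have <- as.integer(tab[best])
    if (have < want) {
      # too rare everywhere: copy the allele onto random other haploids
      cand <- which(s != allele)
      if (length(cand) < want - have)
        stop("cannot reach causal target frequency at this sample size")
      pick <- sample(cand, want - have)
      av <- as.integer(strsplit(allele, "")[[1]])
      pool[pick, first:last] <- matrix(av, length(pick), span, byrow = TRUE)
      edited <- length(pick)
    } else {
      # too common: mutate surplus copies at one flanking site
      pick <- sample(which(s == allele), have - want)
      pool[pick, first] <- 1L - pool[pick, first]
      edited <- length(pick)
    }
    s <- do.call(paste0, as.data.frame(pool[, first:last, drop = FALSE]))
  }
  realized <- mean(s == allele)
  if (abs(realized - target_freq) / target_freq > 0.25)
    warning(sprintf("planted allele realized frequency %.4g misses target %.4g",
                    realized, target_freq))
  list(pool = pool, first_idx = first, last_idx = last,
       allele_string = allele, realized_freq = realized, edited = edited)
}

#' Plant a causal haplotype allele in an existing panel
#'
#' Selects, within a span of consecutive SNPs around \code{locus}, the
#' observed haplotype allele whose frequency is closest to
#' \code{target_freq}; when no allele is within 25\% relative error the
#' panel's haploids are minimally edited (copies added or removed) to reach
#' it.  Returns the allele definition for a truth ledger together with the
#' (possibly edited) panel.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param locus central SNP index of the desired span.
#' @param target_freq desired allele frequency, in (0.005, 0.5).
#' @param span number of consecutive SNPs (>= 5).
#' @return list: \code{panel}, \code{first_idx}, \code{last_idx},
#'   \code{allele_string}, \code{realized_freq}, \code{edited} (number of
#'   haploids modified).
#' @export
plantCausalHaplotype <- function(panel, locus, target_freq, span = 8L) {
  if (target_freq <= 0.005 || target_freq >= 0.5)
    stop("target_freq must be in (0.005, 0.5)")
  if (span < 5L) stop("span must be at least 5 SNPs")
  pl <- .plant_in_pool(panelHaplotypes(panel), locus, target_freq, span)
  panel@haplotypes <- pl$pool
  pl$pool <- NULL
  c(list(panel = panel), pl)
}

#' Write the simulation truth ledger as JSON
#'
#' @param truth the \code{truth} element of \code{\link{simulateCohort}}.
#' @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  truth$causal_dosages <- NULL
  truth$pedigree <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
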