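---
title: "Haplotype-based association scans with mixed linear models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based association scans with mixed linear models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model behind each exported function, the assumptions it rests on, the
tunable parameters and their defaults, what the synthetic cohort generator
does and does not emulate, and the numerical decisions taken where the
design was genuinely open. Nothing here states an empirical result that the
test suite does not itself compute.

## 1. The analysis problem

Case–control association scans built on single genotyped SNPs capture a
causal variant only through its pairwise LD with one marker. A haplotype —
the ordered allele string carried on one inherited chromosome copy across a
set of nearby SNPs — aggregates the LD information of many flanking
markers and can tag rarer untyped variants, particularly in cohorts with
substantial identity-by-descent sharing (families). `haploscan` implements
a genome-wide haplotype scan for a **binary trait** in a **family-structured
cohort**, with a population-based second cohort used for replication and
meta-analysis.

The pipeline consumes *phased* diploid genotypes (VCF with `|`-separated
GT), a recombination map (HapMap-style four-column text: chromosome, bp,
rate in cM/Mb, cumulative cM) and a phenotype/covariate table. Phasing
itself is out of scope: the readers reject unphased or missing calls rather
than guessing, because every downstream statistic assumes two complete
haploid sequences per individual. Multi-allelic sites are likewise
rejected; allele strings are recorded over 0/1 alt-allele codes, not
nucleotide letters, which keeps them strand-unambiguous within a run but
requires identical ref/alt orientation between cohorts (the package does
not attempt cross-cohort strand reconciliation; see §8).

## 2. Window tiling on the genetic map

SNP bp positions are mapped to centimorgans by piecewise-linear
interpolation of the cumulative map column (`interpolateCm`), clamped at
the map ends. Windows of genetic length 1, 0.5 and 0.25 cM are anchored at
the cM position of each chromosome's first SNP and advanced by a quarter of
the window size while the anchor lies before the last SNP
(`tileWindows(step_fraction = 0.25)`). A window collects SNPs with cM in
the half-open interval `[anchor, anchor + size)`; windows with fewer than
five SNPs are dropped.

Open choices, resolved as follows:

- **Anchor origin.** Tiling could start at cM 0 of the map or at the first
  SNP. We anchor at the first SNP: it is deterministic given the data,
  avoids empty leading windows, and makes the first window's left edge
  coincide with the first marker. Both conventions produce the same
  interior windows up to a phase shift of less than one step.
- **Duplicate window content.** Quarter-stepping frequently yields
  consecutive windows containing the identical SNP set (in sparse
  stretches). These are *not* deduplicated: the scan's bookkeeping counts
  windows as tiled, and LD clumping downstream collapses identical test
  results anyway.
- **Truncated tails.** Windows extending past the last SNP are kept when
  they still hold ≥ 5 SNPs.

## 3. Haplotype alleles, frequency, HWE and QC

Within a window, each distinct haploid string *A* defines one "allele";
everything else is pooled into the alternative *a* (`callHaplotypes`).
Diploid class counts (AA, Aa, aa) give the frequency

$$p = \frac{2\,obs(AA) + obs(Aa)}{2\,(obs(AA) + obs(Aa) + obs(aa))}$$

and a Hardy–Weinberg goodness-of-fit statistic with expectations
$(p^2 n,\; 2pq n,\; q^2 n)$:

$$X^2 = \sum_{c \in \{AA, Aa, aa\}} \frac{(obs_c - exp_c)^2}{exp_c}.$$

Three classes minus one estimated parameter leave 1 degree of freedom, so
the QC cut-off `X² > 24` corresponds to HWE *P* < 10⁻⁶
(`hweTailProb(24)` ≈ 9.6 × 10⁻⁷). `qcFilter` flags alleles with
`p < 0.005`, `p > 0.995` or `X² > 24` as *merged*: excluded from testing
but retained inside the pooled alternative of every tested allele, so the
per-window dosages still sum to 2 per individual. The frequency bounds are
inclusive and the HWE bound strict — an allele at exactly `p = 0.005` or
`X² = 24` is kept.

Two deliberate readings: the squared Pearson form is used for `X²` (an
unsquared difference sum has expectation ≈ 0 and cannot be referred to a
χ²₁ scale), and the frequency exclusion is "outside [0.005, 0.995]".
Genotype-class counts are pooled across related individuals; relatedness
inflates the HWE statistic's variance slightly, which is conservative in
the direction of excluding more alleles, and the test is used only as a
QC screen, never for inference.

`haplotypeDosage` codes each individual 0/1/2 by exact haploid string
match. Frequencies used for QC come from all individuals; when a founder
indicator is supplied, a founders-only frequency is reported alongside for
comparison with catalogues computed on unrelated subsets.

## 4. Genomic relationships

`computeGrm` builds the SNP-based genomic relationship matrix

$$G_{jk} = \frac{1}{M} \sum_{i=1}^{M}
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}$$

from hard-call alt dosages at the MAF ≥ 0.01 autosomal SNPs
(`snpDosages(maf_min = 0.01)`). Centring/scaling frequencies default to
sample estimates (configurable, e.g. to founders-only); monomorphic SNPs
are excluded with a warning. Note one consequence exercised in the tests:
with sample-estimated frequencies each SNP's centred column sums to zero,
forcing the mean off-diagonal to −1/(n−1); expectations of 0 for unrelated
pairs hold under the true (or external) frequencies.

`thresholdGrm` zeroes off-diagonals strictly below 0.05 (entries at 0.05
are retained, diagonals untouched), giving the companion matrix **G_t**
that carries only close-family relationships; it is stored sparse but the
contract is value-level. Fitting **G** alone in a family cohort leaves
residual stratification; adding **G_t** as a second random effect absorbs
the excess family resemblance (including shared environment loading on
close relatives) — the two-matrix model is the default for discovery-style
cohorts (`two_grm = TRUE`), the single-matrix model for population-based
replication cohorts.

## 5. The mixed-model scan

The trait enters on the observed 0/1 scale in a *linear* mixed model

$$y = X\beta + Z_1 u + Z_2 v + \varepsilon, \qquad
u \sim N(0, G\sigma^2_u),\;
v \sim N(0, G_t\sigma^2_v),\;
\varepsilon \sim N(0, I\sigma^2_\varepsilon),$$

with fixed effects: intercept, sex, age, age², optional batch and centre
factors, and — when testing — the haplotype dosage. No liability
transformation is applied in the scan; the observed-scale linear treatment
of a binary trait is the standard mixed-linear-model association
convention, valid for testing and approximately valid for effect sizes at
moderate prevalences.

**Estimation.** `remlFit` maximises the restricted likelihood by
average-information (AI) updates with an EM fallback whenever an AI step
would leave the parameter space or reduce the likelihood (plus step-halving
against overshoot). Components are constrained non-negative with a floor of
10⁻⁸ · var(y); convergence is |Δ log-lik| < 10⁻⁸ within 200 iterations.
With a single relationship matrix the model is rotated into the eigenbasis
of **G**, making V diagonal and each iteration O(n p²) — the dense and
eigen paths agree to the convergence tolerance (tested). A relationship
matrix numerically equal to I is rejected as unidentifiable (aliased with
the residual); a non-PSD V after a 10⁻⁶ diagonal jitter is an error.

**Testing.** Variance components are estimated once under the null (no
haplotype term) and reused for every haplotype — the standard
leave-nothing-out MLMA convention, chosen for tractability; per-haplotype
refitting would rescale each test marginally at ~100× the cost. V is
factorized once per scan; `scanHaplotypes` runs all dosages through the
cached GLS projection in one matrix operation. The Wald statistic for
dosage *d* is

$$\hat\beta = \frac{d^\top P_0 y}{d^\top P_0 d}, \qquad
SE = (d^\top P_0 d)^{-1/2}, \qquad
P_0 = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1},$$

with a two-sided normal P. Constant dosages are skipped
("monomorphic in analyzed set"); dosages in the span of the fixed effects
are an error ("aliased covariate"). Aliased fixed-effect columns are
dropped deterministically, later columns first.

**Odds ratios.** The model is linear, so effects are risk differences on
the observed scale. For reporting, `betaToOr` applies the first-order
conversion log OR ≈ β / (cf·(1−cf)) at the sample case fraction cf, CI
endpoints transformed identically. This is exact as β → 0 and
underestimates slightly for large effects; `logisticOr` provides an exact
logistic refit (ignoring relatedness) as a cross-check, and the tests hold
the two within 5 % for OR ≤ 2. Published downstream (meta-analysis) uses
the log-OR scale throughout.

**Variance explained.** A tested allele's population-level contribution is
2p(1−p)β². Because the natural denominator is ambiguous (phenotypic
variance vs. the summed genetic variance components), both fractions are
emitted (`var_fraction`, `var_fraction_genetic`) and the raw quantity is
kept alongside.

**Diagnostics.** `genomicInflation` returns the median implied χ²₁
statistic divided by qchisq(0.5, 1) = 0.4549364 (the constant is carried at
full precision, documented here to the digit). Scans with ≥ 100 tests
report λ_GC automatically.

## 6. Fine mapping of haplotype boundaries

A window-allele test compares *A* against *everything else in that
window* — including near-identical haplotypes carrying the same causal
variant, which dilutes the contrast. Fine mapping addresses this: pairs of
same-size-class alleles whose windows share ≥ 5 consecutive SNPs, each
with *P* below 10⁻³ and concordant effect sign, are intersected
(`findCandidatePairs`); every shared consecutive run of ≥ 5 agreeing SNPs
becomes a refined haplotype (`sharedConsecutiveRegion`) — all qualifying
runs, not just the longest, since one pair can legitimately yield several
refined candidates. Refined alleles are re-tested in all individuals with
the same null-model covariance as the main scan (`fineMap`). Two structural
invariants are tested: refinement never leaves the union of the parent
windows, and a refined allele's frequency is at least the maximum of its
parents' (its carriers are a superset). Refined haplotypes inherit the main
scan's multiple-testing context; their P-values are reported alongside,
not re-corrected. "Directly overlapping" is operationalised as ≥ 5 shared
consecutive SNPs in the same size class — adjacent quarter-step windows
always qualify; pairs are not restricted to adjacent offsets only.

## 7. Clumping, meta-analysis, power

**Clumping** (`clumpResults`) counts approximately independent signals the
way PLINK's clump command does: sort by ascending P (ties by chromosome,
then start position), promote each unassigned haplotype to a clump index,
and absorb every unassigned haplotype within 1,000 kb (window midpoints)
whose dosage r² with the index reaches 0.4. The Bonferroni level is
0.05 / n_independent. The distance default is configurable (the clumping
radius is a convention, not an estimate); r² is computed on all analysed
individuals.

**Meta-analysis** (`ivwMeta`) is fixed-effect inverse-variance weighting on
the log-OR scale: weights 1/se², combined β = Σwβ/Σw, se = (Σw)^−1/2.
Closed-form identities (k equal cohorts shrink se by √k; an infinitely
noisy cohort contributes nothing) are tested exactly. `orCiToBetaSe`
recovers (β, se) from published OR (95 % CI) rows via
se = (ln hi − ln lo)/(2·1.959964), enabling meta-analysis of printed
summary tables. Random-effects models and heterogeneity statistics are out
of scope.

**Power** (`allelicPower`). Under a multiplicative per-allele risk model
with population haplotype frequency f, genotype relative risk GRR and
trait prevalence K, the case-chromosome frequency is
p_case = f·GRR / (1 + f·(GRR − 1)); screened controls (trait-free by
ascertainment) have p_ctrl = (f − K·p_case)/(1 − K). Power is that of the
1-df two-proportion z-test on 2·n_case vs 2·n_control chromosomes at
two-sided α. At GRR = 1 the function returns exactly α; it is monotone in
GRR, f (below 0.5) and n, and agrees with a Monte-Carlo oracle that
simulates allele counts and applies the same test within ±0.02 (tested).
The default prevalence for replication sizing is K = 0.146, the
clinically ascertained MDD prevalence reported for comparable high-income
populations.

## 8. The synthetic cohort generator

No individual-level genotypes accompany the study design this package
implements (such cohorts are access-controlled), so `simulateCohort` is a
first-class module: everything the statistics claim is demonstrated on
cohorts it generates.

What it emulates, and the defaults:

- **Family structure.** Family sizes are drawn from a singleton-heavy
  distribution with support 1–31 shaped like a family-based cohort's
  census (many singletons; ~1,800:1,800:1,200:830 relative mass at sizes
  1–4 and a geometric tail to 31). Families are founders plus children; in
  larger families later members may descend from earlier non-founder
  members (three generations) through unobserved spouses, yielding a mix
  of parent–offspring, sib, half and grandparental relationships.
- **Haplotypes and LD.** Founder haploids follow a first-order Markov
  chain: at each SNP the latent uniform driving the allele call is copied
  from the previous SNP with probability `founder_ld` (default 0.9) or
  refreshed — giving blocky, controllable LD with correlation decaying
  geometrically in marker count. This is deliberately simpler than
  coalescent simulation: desk-scale speed and explicit control of
  haplotype frequencies outweigh realism of the allele-frequency spectrum.
- **Map.** Positions are jittered-uniform over `map_length_cm` Mb at an
  overall 1 cM/Mb, with per-segment lognormal rate variation
  (`rate_sd = 0.3`), emitted as a standard four-column map.
- **Meiosis.** Gametes are crossover mosaics with crossover counts
  Poisson(L/100 per morgan) and positions uniform on the cM map —
  Mendelian consistency is tested exhaustively on small pedigrees and
  realized GRM entries average ≈ 0.5 (sibs, parent–offspring) and ≈ 0
  (founders).
- **Phenotype.** Liability = sex/age/age² covariate effects (defaults 0.1,
  0.1, 0.05; ages uniform 18–99, sex Bernoulli(0.5)) + planted causal
  dosage effects + pedigree-correlated polygenic term (h² = 0.3 by
  default; child g = midparent + N(0, h²/2)) + unit-scale residual. An
  individual is a case when liability exceeds the *empirical* (1−K)
  quantile, so realized prevalence tracks K by construction; default
  K = 0.139 (discovery-like), 0.340 for replication-like cohorts.
- **Planted effects.** `plantCausalHaplotype` selects the observed allele
  string over a span of consecutive SNPs closest to the target frequency
  and, only when no allele is within 25 % relative error, minimally edits
  founder haploids (copying the allele in, or mutating surplus copies at
  one flanking site). The truth ledger records the allele, its realized
  frequency, the liability effect and the number of edited haploids.
- **Reproducibility.** All randomness flows from one seed through named
  substreams (map, pedigree, frequencies, founders, meiosis, phenotype).
  A separate `map_seed` lets a discovery/replication pair share its SNP
  panel — positions, cM, frequencies — while drawing independent founders
  and phenotypes, and causal entries can force an explicit allele string
  so both cohorts carry the same causal allele.

What it does **not** emulate: coalescent/ARG genealogies and realistic
allele-frequency spectra, genotyping and phasing error, imputation
uncertainty, X chromosomes, assortative mating, and ascertainment beyond
the liability threshold. Passing tests therefore demonstrate the
statistical machinery under idealised phased data — calibration and
recovery claims transfer to real cohorts only to the extent that phasing
is accurate and the trait approximates the liability model.

## 9. Problem sizes and numerical choices

Test-suite problem sizes are the package's own desk-scale choices: REML
parameter recovery uses 200 replicates of 100 five-member families
(n = 500) with true components (0.5, 0.5); null-scan calibration uses one
cohort of n = 2,000 with 4,000 SNPs over 25 cM, non-overlapping 0.25 cM
windows (several hundred tested alleles; KS uniformity and
λ_GC ∈ [0.95, 1.05]); end-to-end recovery plants a 25-SNP causal allele at
frequency 0.15 with liability effect 0.6 in 20 cohorts of n = 800 and
requires the causal window among the top-10 hits in ≥ 90 % of replicates.
The planted effect size was fixed a priori by the observed-scale power
heuristic β_obs ≈ β_liab·φ(τ) (τ the liability threshold) targeting ~80 %
power at a 10⁻⁵ design alpha; the causal span matches the 0.25 cM window
SNP count because a much shorter causal core fragments across window-length
alleles — which is precisely the dilution phenomenon fine mapping exists
to undo, and the fine-mapping tests cover it.

Numerical details worth knowing:

- Cholesky factorizations get one 10⁻⁶·mean(diag) jitter retry; failure is
  an error, never silent regularisation.
- Variance components are floored at 10⁻⁸·var(y), so "zero" components are
  reported as the floor; `RemlFit@converged` records whether the
  log-likelihood tolerance was met.
- Clump ties in P are broken by chromosome then start position, making the
  partition invariant to input order (tested).
- λ_GC uses qchisq(0.5, 1) at machine precision, not a rounded 0.455.
- Summary TSVs round-trip at 12 significant digits; `write_json` uses
  `digits = NA` (no rounding).
- Window/SNP coordinates are 1-based inclusive throughout; only the BED
  export converts to 0-based half-open.

## 10. Known limitations

- The observed-scale linear model reports risk-difference effects; OR
  conversion is approximate (flagged above) and the package deliberately
  reports both the conversion and the logistic cross-check rather than
  pretending they are one number.
- Dosage Wald tests on very rare alleles (p near the 0.005 floor) are
  slightly conservative at moderate n — visible as λ_GC marginally below 1
  in the calibration test.
- The two-GRM model treats G_t's extra variance as genetic/family; it
  cannot separate shared environment from close-pedigree genetics.
- Haplotype uncertainty is ignored: input phase is taken as truth.
- Diplotype (haplotype-pair) models and dominant codings are not
  implemented; the scan is additive.
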