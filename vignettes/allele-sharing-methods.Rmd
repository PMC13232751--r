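---
title: "Allele-sharing estimation of descent measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-sharing estimation of descent measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleshare)
library(dplyr)
```

## The model

Inbreeding, kinship and population structure are all *descent measures*:
correlations of allelic-state indicators for a pair of alleles, or
equivalently probabilities that the two alleles are identical by descent
(ibd). A descent measure is never absolute. It is always defined relative to
a *reference set* of allele pairs in which alleles are taken as unrelated:
the pairs of distinct individuals in the target's own population, all pairs
of individuals in the study, or pairs of alleles in distinct populations.

For a variant with designated-allele probability $\pi$ and a pair of alleles
with descent measure $\theta$, the probability the pair is identical in
state is $1 - 2\pi(1-\pi)(1-\theta)$ for diploid indicator pairs. The
observable counterpart of $\theta$ is the *allele-sharing statistic*
$\tilde A$: the proportion of distinct allele pairs identical in state.
Within a diploid individual with dosage $X$ it is $(X-1)^2$ (1 for
homozygotes, 0 for heterozygotes); between two individuals it is
$[XX' + (2-X)(2-X')]/4$. Since
$E(\tilde A) = 1 - 2\pi(1-\pi)(1-\theta)$, the ratio

$$\hat\theta_{Y|R} \;=\; \frac{\sum_\ell (\tilde A_{Y,\ell} - \tilde A_{R,\ell})}
{\sum_\ell (1 - \tilde A_{R,\ell})}$$

estimates the compound parameter $(\theta_Y - \theta_R)/(1 - \theta_R)$ for
target pairs $Y$ relative to reference set $R$ without ever estimating
$\pi$: the nuisance factor $2\pi(1-\pi)$ cancels from numerator and
denominator. Summing over variants *before* dividing (a ratio of averages,
never an average of ratios) is what makes the multi-locus estimator converge
to the compound parameter as the variant count grows.

Two structural consequences are worth stating because the package tests
them exactly:

* the average estimated kinship over all distinct pairs in the reference
  set itself is identically zero (within each population for the
  within-population reference; over all pairs for the whole-study
  reference; over population pairs for the between-population reference);
* changing the reference set applies a positive-slope affine map
  $\hat k' = [(1-\tilde A_R)\hat k + (\tilde A_R - \tilde A_{R'})] /
  (1-\tilde A_{R'})$ to every estimate, so rankings are invariant. Setting
  $\tilde A_{R'}$ to the smallest target sharing reproduces the
  minimum-referenced convention in which the least related pair scores
  exactly zero (`rescale_reference(..., "minimum")`).

The comparator estimators are included with their known expectations:
dosage-centered "standard" kinship (expectation
$k_{jj'} - \bar k_j - \bar k_{j'}$, hence reference-dependent rankings),
KING-robust (kinship relative to the pair's own inbreeding,
$(\theta_{jj'} - \bar F)/(1-\bar F)$), Li–Horvitz (targets $f_{IS}$, not
$F_I$), Nei's 1973 and 1986 $F_{ST}$ (the 1986 revision is algebraically
the allele-sharing $F_{SB}$), the Weir–Cockerham 1984 ANOVA (identical to
$F_{SB}$ at equal sample sizes), Hudson's allelic estimator (targets the
distinct-allele measure $F_{DB}$), and the $f_2/f_3/f_4$ admixture
statistics.

## Parameters that matter

* **Reference set** (`reference` in `as_inbreeding()`, `as_kinship()`):
  `within_population`, `whole_study` or `between_populations`. The choice
  changes the location and scale of every estimate but never their order.
  `as_fst()` always uses the between-population reference, the natural one
  for population-level F-statistics.
* **Ploidy** $\kappa$ (default 2, constant per panel): between-individual
  sharing generalises to $[XX' + (\kappa-X)(\kappa-X')]/\kappa^2$ and
  self-coancestry to $[1+(\kappa-1)F]/\kappa$. Haploids have no
  within-individual allele pair, so inbreeding is undefined for them and
  self-coancestry is identically 1.
* **Block size** in `block_bootstrap()` (default 100 variants):
  non-overlapping contiguous blocks in genome order; large enough to span
  local linkage disequilibrium, small enough to leave many blocks.
  Overlapping blocks were deliberately not implemented; with independent
  loci any block size gives equivalent intervals, which the tests check.
* **Confidence level** (default 0.95) with percentile intervals: the
  simplest interval consistent with bootstrapping a ratio statistic; no
  analytic variance is attempted because closed forms for the genetic
  sampling variance of these ratios are impractical.

## Numerical and design choices

* **Missing data.** Every statistic is an average over the typed
  individuals or pairs at each variant, and every ratio sums over the
  variants where its target is typed — proportions of typed variants, not
  of all variants. A statistic with no typed contributors is `NA`, never
  zero. Under heavy missingness the per-pair denominators differ, so the
  zero-mean identities above hold exactly only for complete data (the
  pooled ratio remains exactly zero); this bias is documented, not
  corrected.
* **Half-called genotypes** in VCF input are treated as fully missing:
  conservative, and it keeps dosages integral.
* **Monomorphic variants are retained.** They carry information about the
  reference sharing level and never cause division on their own because
  division happens once, after summation. No minor-allele-frequency or LD
  filtering is applied anywhere by default.
* **Multiallelic variants** are split into one biallelic layer per
  alternate allele; layers enter the sums like additional variants. For
  biallelic variants the two alleles give identical estimators, so a single
  designated allele suffices.
* **Within-individual sharing for polyploids** uses distinct-pair
  enumeration $[X(X-1) + (\kappa-X)(\kappa-X-1)]/[\kappa(\kappa-1)]$, which
  reduces to $(X-1)^2$ at $\kappa = 2$. The diploid form is the standard
  one; the polyploid generalisation is this package's choice, validated
  against an explicit allele-pair enumeration oracle
  (`brute_force_sharing()`).
* **Population averages are unweighted**, with one deliberate exception:
  the study-average within-population inbreeding pools numerators and
  denominators, which is equivalent to weighting population-specific
  $\hat f_{IS}^i$ by $(1-\tilde A_S^i)$ — the combination for which the
  pooled ratio identity holds.
* **Estimates below $-1$ are reported as-is**; clamping would destroy the
  affine reference-change relation.
* **"Exact" identities** (WC84 ≡ AS at equal $n$, Nei-1986 ≡ AS, zero
  means, rank invariance) are asserted at $10^{-12}$.
* **f-statistics** use the study-wide $1-\tilde A_B$ as a common
  denominator so values are comparable across population subsets, and are
  defined with the factor-$\frac12$ convention under which the $f_2$
  numerator reduces to $(\tilde p_i - \tilde p_{i'})^2$ and the $f_3$
  numerator to $(\tilde p_c - \tilde p_a)(\tilde p_c - \tilde p_b)$ when
  sharing is expressed through sample frequencies. Under that convention
  $f_3$ of a focal population drifted by $\theta_S$ away from independent
  partners has expectation $\theta_S/2$ (not $\theta_S$), which is what the
  tests assert.
* **Drift expectation.** `drift_theta()` uses the complement form
  $1-\theta_t = (1-\theta_{12})(1-\tfrac{1}{2N})^t$, under which identity
  decays geometrically and $\theta_t \to 1$; the log-identity
  $\log[(1-\theta_t)/(1-\theta_{12})]$ is the quantity linear in time and
  hence usable as a drift distance.

## What the simulator emulates — and what it does not

`sim_panel()` draws per-population frequencies from a Beta distribution
with mean $\pi$ and variance $\pi(1-\pi)\theta_i$ (the Balding–Nichols
parameterisation) and genotypes with a two-state inbreeding mixture: with
probability $f$ all allele copies of an individual duplicate a single draw,
otherwise copies are independent. This is the simplest generator satisfying
the expectations the estimators are built on
($E(\tilde A) = 1-2\pi(1-\pi)(1-\theta)$, with
$F_I = f + (1-f)\theta$, $\theta_S = \theta$, $\theta_B = 0$), and it
returns its true parameters so recovery can be asserted. It does **not**
emulate linkage disequilibrium, allele-calling error, mutation or selection,
non-zero between-population coancestry, or continuous inbreeding variation
within a population — so passing recovery tests demonstrate estimator
correctness under the model, not robustness to everything real data do.
`gene_drop()` complements it with pedigree-realised ibd (tracked founder
labels), and `sim_admixed_panel()` builds a deliberately unbalanced
two-ancestry study (a large source panel, a small one, and an admixed
population with individual admixture proportions) because that is the
situation in which dosage-centered kinship re-ranks pairs when the
reference sample changes while allele-sharing kinship does not.

Problem sizes used by the test suite were chosen to make Monte-Carlo error
small relative to the assertions: expectation-recovery runs use one to five
populations of 50–100 individuals and 10{,}000 variants with about ten
replicates (the variant count at which multi-locus allele-sharing
estimation is generally considered to perform satisfactorily), and bootstrap
coverage uses 200 replicate experiments of 1{,}000 variants.

## A worked example

```{r example}
sim <- sim_panel(n_pops = 3, n_ind = 30, n_loci = 4000,
                 theta = c(0.02, 0.05, 0.10), f = 0.05, pi = c(0.1, 0.9),
                 seed = 42)
fst <- as_fst(sim$panel)
fst

glance(as_inbreeding(sim$panel, reference = "within_population"))

bb <- bootstrap_fst(sim$panel, block_size = 50, B = 500, seed = 1)
tidy(bb)
```

The overall $\hat F_{SB}$ estimates the average within-population kinship
relative to between-population allele pairs — here the simulated average
differentiation $\bar\theta \approx 0.057$ — and the per-population
$\hat F_{SB}^i$ recover the population-specific $\theta_i$. The
within-population $\hat f_{IS}$ targets $(F_I-\theta_S)/(1-\theta_S)$,
about $0.05$ under this generator.

## Known limitations

* Absolute ibd probabilities are not estimable from contemporary samples;
  everything here is "relative to", and outputs are tagged with their
  reference set to keep that visible.
* Heavy missingness can bias estimates because reference aggregates are
  computed from different typed subsets per variant; no imputation is
  attempted.
* The WC84 implementation reproduces the classical sample-size-weighted
  ANOVA; the paper-level identity with allele sharing is exact only at
  equal sample sizes, and the equal-$n$ identity test is the guard against
  transcription error in the mean squares.
* Mixed-ploidy cohorts are rejected; phased data, haplotype sharing and
  segment-based ibd are out of scope.
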