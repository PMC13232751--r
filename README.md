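# alleleshare

Estimation of descent measures — individual inbreeding, pairwise kinship
(coancestry) and population-level F-statistics — from SNP dosage data with
**allele-sharing statistics**, always relative to an explicit **reference set
of allele pairs**. For population and quantitative geneticists who need
relatedness or structure estimates whose rankings do not depend on which
individuals happen to be in the study.

## The statistic at the core

Descent measures (the correlation of allelic indicators, or the probability
of identity by descent, for a pair of alleles) are not absolute: they only
exist relative to a reference set *R* of allele pairs taken as unrelated.
The observable surrogate of a descent measure is the allele-sharing
proportion *Ã* — the fraction of distinct allele pairs identical in state.
For diploid dosages *X* (copies of a designated allele):

- within an individual: *Ã<sub>j</sub>* = (X − 1)² — 1 for homozygotes, 0
  for heterozygotes;
- between individuals: *Ã<sub>jj′</sub>* = [XX′ + (2 − X)(2 − X′)]/4 — 1,
  0, or 0.5 for the same-homozygote, opposite-homozygote, and
  heterozygote-involving configurations.

Because E(*Ã*) = 1 − 2π(1 − π)(1 − θ), the ratio of averages

&nbsp;&nbsp;&nbsp;&nbsp;θ̂<sub>Y|R</sub> = Σ<sub>ℓ</sub>(Ã<sub>Y,ℓ</sub> − Ã<sub>R,ℓ</sub>) / Σ<sub>ℓ</sub>(1 − Ã<sub>R,ℓ</sub>)

estimates (θ<sub>Y</sub> − θ<sub>R</sub>)/(1 − θ<sub>R</sub>) without ever
estimating allele probabilities, and changing *R* applies a positive-slope
affine map — estimates keep their ranks under any reference change, which
sample-frequency-based estimators do not. The package provides the full
estimator family (inbreeding, kinship matrices with diagonal (1 + f̂)/2,
overall/per-population/pairwise F-statistics), the comparators analysed
against it (dosage-centered "standard" kinship, KING-robust, Li–Horvitz,
Nei 1973/1986, Weir–Cockerham 1984 ANOVA, Hudson's allelic estimator,
f2/f3/f4), pedigree path-counting coancestry and gene-dropping, a
Balding–Nichols panel simulator with known truth, and block-bootstrap
confidence intervals. Polyploid and haploid dosages, multiallelic VCF
records (split into per-allele layers) and missing genotypes are supported.

## Worked example

```r
library(alleleshare)

sim <- sim_panel(n_pops = 3, n_ind = 30, n_loci = 4000,
                 theta = c(0.02, 0.05, 0.10),  # per-population drift
                 f = 0.05, pi = c(0.1, 0.9), seed = 42)
as_fst(sim$panel)
#> <as_fst> 4000 variants
#>   F_IB = 0.100012
#>   F_SB = 0.056076
```

`F_SB` — the allele-sharing analogue of Wright's F<sub>ST</sub>, average
within-population kinship relative to between-population allele pairs —
recovers the simulated mean differentiation θ̄ ≈ 0.057; `F_IB` recovers the
inbreeding measure F<sub>I</sub> = f + (1 − f)θ ≈ 0.10. The
population-specific values track each θ<sub>i</sub> (0.016, 0.053, 0.099
for truths 0.02, 0.05, 0.10), and the within-population inbreeding averages
sit at the model value f<sub>IS</sub> = 0.05:

```r
glance(as_inbreeding(sim$panel, reference = "within_population"))
#> # A tibble: 4 × 5
#>   pop     value   num   den n_variants
#> 1 pop1   0.0520  79.8 1535.       4000
#> 2 pop2   0.0462  68.3 1479.       4000
#> 3 pop3   0.0410  57.7 1406.       4000
#> 4 .study 0.0465  68.6 1473.       4000

tidy(bootstrap_fst(sim$panel, block_size = 50, B = 500, seed = 1))
#> # A tibble: 1 × 7
#>   estimate conf.low conf.high level     B block_size n_excluded
#> 1   0.0561   0.0541    0.0582  0.95   500         50          0
```

Kinship matrices come from `as_kinship(panel, reference = ...)` (tidy with
`tidy()`, heatmap with `autoplot()`); `rescale_reference()` re-expresses any
estimate set against a new reference, including the minimum-zero convention.
`read_vcf_panel()` / `read_dosage_tsv()` bring in real data.

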