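# admixdyn

Temporal dynamics of genomic ancestry in recently admixed cohorts.

Admixed populations in the Americas carry varying proportions of
Amerindigenous (AI), European and African ancestry, and those proportions
are not static: in Mexican American community cohorts, mean AI ancestry
rose by roughly 20% across birth years spanning the 1940s to the 1990s.
`admixdyn` implements the computational machinery for studying such
shifts and their consequences for complex-trait genetics:

* a **Moran-model forward simulator** of genome-wide ancestry
  proportions. Each elementary step replaces one individual (N steps ≈
  one generation), under four forces: ancestry-based assortative mating
  of strength *AM* ∈ [0,1] (the second parent is the first parent's
  nearest neighbour in ancestry with probability *AM*); ancestry-based
  fecundity differences *FAI* ≥ 0 (the reproducing parent sits at the
  ancestry-rank quantile drawn from Beta(1, 1+*FAI*), measured from the
  top of the ranking); migration (*M*, *mAI*); and exponential growth;
* the **ancestry-trend regressions** of the epidemiological design:
  Ancestry = β₀ + β₁·BY + β₂·SW + ε, with BY the birth year and SW the
  natural log of the survey sampling weight, plus stratified fits,
  bootstrap-LOESS envelopes, and a quantile-normalized 69-trait
  association harness;
* **diversity inside local-ancestry tracts**: nucleotide diversity π
  (pairwise differences between AI-labelled haplotype segments of
  distinct individuals) and F_ST = (H_T − H_S)/H_T between birth
  decades, plus the tract-length distribution regression
  log f = β₀ + β₁T + β₂A + β₃TA;
* **runs of homozygosity**: three-component Gaussian-mixture size
  classes (fixed study boundaries 845,097 bp and 2,501,750 bp, or
  refitted), diploid overlap of ROH with per-haplotype ancestry tracts,
  and Kendall-τ birth-year trends;
* **admixture mapping** of birth year on local AI-ancestry dosage with
  an effective-number-of-tests threshold from an autoregressive estimate
  of the number of ancestral blocks;
* a **polygenic height score**: lowest-p-per-1-Mb-window SNP selection
  from GWAS summary statistics, dosage-weighted scoring, and
  height-score association stratified by quartiles of global AI
  ancestry (the portability analysis);
* a **synthetic cohort generator** that emulates the study's data
  structure end to end (cohort table with birth years 1934–1993 and
  sampling weights, 3-way global ancestry, phased local-ancestry tracts,
  tract-conditional genotypes under Balding–Nichols panel divergence,
  ROH, GWAS summary statistics and a height phenotype), so every
  analysis is testable without restricted data access.

## Worked example

Simulate two generations of joint assortative mating (AM = 0.75) and
fecundity forcing (FAI = 0.8) in a population of 1000 with initial mean
AI ancestry 0.42:

```r
library(admixdyn)
tr <- moran_run(moran_params(AM = 0.75, FAI = 0.8), seed = 1)
tr
#> Moran trajectory: 41 records, 2000 matings
#>   mean ancestry 0.4210 -> 0.4974 (+18.14%), parental r = 0.714
```

The mean rose about 18% over two generations in this replicate (the
force combination that matches the observed cohort-level rise), and the
parental ancestry pairs logged along the way are correlated at 0.714 —
the assortative-mating signature.

Generate a synthetic cohort at the default configuration (n = 3622,
mean AI ancestry 0.489, generating birth-year effect 0.0023/yr) and fit
the ancestry-trend model:

```r
coh <- generate_cohort(cohort_config(), seed = 1)
fit_trend(coh)
#> Trend fit: anc_ai  (n = 3622 , R^2 = 0.0473 )
#>               estimate        se     ci_lo    ci_hi         p
#> (Intercept) -3.6140000 0.3215000 -4.245000 -2.98400 7.560e-29
#> birth_year   0.0020890 0.0001638  0.001768  0.00241 1.678e-36
#> log_weight  -0.0003858 0.0056970 -0.011560  0.01078 9.460e-01
```

The fitted birth-year coefficient (0.00209, 95% CI 0.00177–0.00241)
recovers the generating effect size within sampling error; averaged over
seeds it centres on 0.0023. The cohort's built-in parental ancestries
carry the configured correlation:

```r
parental_correlation(coh$parent1_ai, coh$parent2_ai)[c("r", "ci_lo", "ci_hi")]
#>       r ci_lo ci_hi
#> 1 0.706 0.689 0.722
```

An end-to-end synthetic study (generation → simulation → trends →
tract diversity → ROH → admixture mapping → polygenic score) runs with:

```r
res <- run_pipeline(pipeline_config("tiny", seed = 1))
res$summary
```

## Documentation

The methods vignette (`vignettes/admixture-dynamics.Rmd`) describes the
simulator's event loop and parameter semantics, the synthetic
generator's statistical assumptions and their limits, and the numerical
conventions (coordinate system, tie rules, pseudo-counts, degenerate
inputs) used throughout.
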