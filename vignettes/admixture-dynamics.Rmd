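---
title: "Modelling temporal shifts in genomic ancestry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal shifts in genomic ancestry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixdyn` studies how genome-wide ancestry proportions in a recently
admixed population change across birth cohorts, and what such change does
to the genetic architecture of complex traits. This vignette records the
models, the parameter semantics, and the design decisions behind the
package — in particular those points where the underlying science admits
more than one reasonable reading and a concrete choice had to be made.

## The Moran ancestry simulator

### Event loop

The simulator tracks one heritable quantity per individual: the
genome-wide Amerindigenous (AI) ancestry proportion, a number in [0,1].
The population evolves by Moran replacement events; N events make one
generation, so overlapping generations come for free. One event:

1. With probability `M` the incoming individual is a **migrant**, with
   ancestry drawn from a Beta distribution with mean `mAI` and
   concentration `migrant_concentration` (a point mass when the
   concentration is infinite).
2. Otherwise two parents are chosen. **Parent 1** is the individual at
   ancestry-rank quantile `q` (see the fecundity law below). **Parent 2**
   is, with probability `AM`, parent 1's nearest neighbour in ancestry
   proportion (ties broken uniformly, self excluded) and otherwise a
   uniformly random other individual. The offspring inherits the
   midparent ancestry plus clipped Gaussian noise
   (`offspring_noise_sd`, default 0.02 — a stand-in for the
   recombination variance a sequence-level model would produce).
3. A uniformly chosen resident dies. Under exponential growth,
   scheduled birth-without-death events are interleaved uniformly within
   each generation so the census size tracks
   `N0 * exp(growth_rate * t)`; the number of replacement events per
   generation is re-evaluated at each generation boundary from the
   current size.

Two structural consequences are worth stating because the test suite
leans on them. With `M = 0` and `FAI = 0`, the expected mean ancestry is
a martingale for *any* `AM`: assortative mating redistributes pairings
but draws parents uniformly across the ancestry spectrum, so it cannot
move the mean (it does slow the loss of variance). And a single
replacement event can move the mean by at most 1/N.

### The fecundity law

Ancestry-correlated fecundity is modelled by biasing *which rank* of the
ancestry distribution reproduces. The reproducing parent's rank quantile,
measured from the top of the ranking, is drawn from Beta(1, 1 + FAI);
equivalently, the ascending-rank quantile is Beta(1 + FAI, 1). At
`FAI = 0` this is uniform (no fecundity differences); the mean selection
quantile (1 + FAI)/(2 + FAI) rises monotonically with `FAI`, reaching
2/3 at `FAI = 1`.

A second parameterization of the same idea — drawing the ascending
quantile from Beta(1, 1/(1 + FAI)) — shares all those anchor properties
(uniform at 0, mean 2/3 at 1, monotone) but concentrates far more mass
on the extreme top ranks: it selects the very highest-AI individuals
disproportionately often rather than shifting the whole selection
distribution upward. Under that reading, the canonical joint forcing
`AM = 0.75, FAI = 0.8` drives the mean up by 30–45% over two generations
(depending on the initial spread) instead of the ~20% that combination
is calibrated to produce. We therefore ship the first reading as the
default (`fecundity_rule = "beta-top"`) and expose the second
(`"beta-reciprocal"`) for sensitivity analysis.

### Defaults and calibration

The stated simulation conditions are: `N0 = 1000`, initial mean ancestry
`mean_ai0 = 0.42`, two generations (2N replacement steps). The initial
*spread* of ancestry is not pinned down by those conditions, but it is
constrained by two calibration anchors the simulator is meant to honour
jointly: `AM = 0.75` should reproduce the observed parental ancestry
correlation (about 0.71), and `AM = 0.75` with `FAI = 0.8` should
reproduce the observed cohort-level rise of roughly 20%. The parental
correlation under the nearest-neighbour rule is essentially `AM` itself,
independent of the spread; the fecundity response scales with the
spread. A Beta concentration of 20 (sd ≈ 0.11 at mean 0.42) satisfies
both anchors and is the default `init_concentration`. These choices were
fixed once, at design time, and the acceptance checks simply re-measure
them.

Mean and variance are recorded every `N0/20` steps; every non-migrant
mating's parental pair is logged, and the trajectory reports their
Pearson correlation — the simulated analogue of the parental-ancestry
correlation estimated from real trios.

## The synthetic cohort generator

The generator produces data with the *statistical structure* the
analyses assume, not a facsimile of any real cohort. Defaults emulate a
Mexican American community-cohort arm: n = 3622; uniform birth years
1934–1993; four recruitment centers with realistic imbalance; ~17.5%
US-born, with 0/1/2 US-born parents distributed 0.61/0.24/0.16 among
them; log-normal sampling weights correlated −0.3 with birth year (the
design oversampled older residents); and three-way ancestry with mean AI
0.489 rising 0.0023 per birth year.

Key modelling choices:

* **Ancestry noise.** Individual AI ancestry is Beta-distributed around
  a linear-in-birth-year mean (clipped to [0.01, 0.99]), reparameterized
  by mean and concentration. Concentration 8 gives sd ≈ 0.17, a
  realistic dispersion for Mexican American cohorts. Linearity of the
  conditional mean is what makes the OLS birth-year coefficient an
  unbiased estimate of the generating slope; configurations whose linear
  mean escapes the clip range over most of the birth-year window are
  rejected rather than silently flattened.
* **Sampling weights** are log-normal. Nothing in the emulated design
  pins the distribution; the log-normal is a stand-in and only its log
  enters any model, as the covariate SW.
* **Parental ancestries** are built symmetrically around the offspring
  value, `p1 = a + d`, `p2 = a - d` with Gaussian `d`, with the
  within-pair spread chosen so the parent–parent correlation equals the
  configured target (0.708 by default).
* **Height** is base + secular trend (0.096 cm/yr) + gender effect +
  an AI-ancestry effect applied to the ancestry *residual* about its
  birth-year mean + noise (sd 6.5 cm). Centering the ancestry effect
  keeps the regression estimand of the birth-year coefficient equal to
  the configured secular trend even though ancestry itself trends with
  birth year. When genotypes are available, `attach_height()` rebuilds
  height with a true polygenic component, and its `ai_attenuation`
  parameter scales the genetic value by `1 - attenuation * anc_ai` to
  emulate the portability decay of European-GWAS effect sizes on AI
  haplotype backgrounds.
* **Local-ancestry tracts** follow a Markov switching process: ancestry
  switch points are Poisson with rate `lambda_gens` per Morgan (the
  admixture age in generations, default 10) and each segment's label is
  an independent draw from the individual's global proportions. The
  stationary distribution is exactly the global proportions, the mean
  tract length of ancestry k is `1/(lambda_gens * (1 - p_k))` Morgans,
  and tracts tile every chromosome. This emulates the *output format and
  first-order statistics* of a local-ancestry caller; it has no linkage
  to genotypes beyond the tract labels and no switch-error process.
* **Genotypes** are Bernoulli draws from the panel frequency of the
  tract ancestry covering each site, with panels diverged from a common
  ancestral frequency by a Balding–Nichols model with parameter
  `fst_target`. Note a classical estimator fact checked in the tests:
  the two-group (H_T − H_S)/H_T computed between two Balding–Nichols
  panels has expectation near `fst_target/2`, not `fst_target` (the
  two-deme correction), and the plain `2p(1-p)` heterozygosity carries a
  positive small-sample bias of about half the reciprocal haplotype
  count — `fst_between_groups(..., unbiased = TRUE)` applies the
  `n/(n-1)` correction.
* **Sites are independent**: there is no linkage disequilibrium within
  panels. Analyses whose power depends on LD structure (clumping beyond
  window selection, LD-aware scores) are out of scope, and test results
  on synthetic data say nothing about LD-driven behaviour on real data.

## Statistical conventions

* **Coordinates** are 0-based half-open everywhere; conversion to
  1-based happens only at the VCF boundary.
* **Quantile normalization** maps values to `qnorm((rank - 0.5)/n)`
  with average ranks for ties; all-tied input is an error.
* **Decades** bin as [d, d+10): the 1940s are 1940–1949.
* **π comparability**: a site enters a haplotype pair's comparison only
  when *both* haplotypes carry the target ancestry there, and pairs
  within one individual are excluded ("across individuals"). π is
  normalized per comparable (pair × site) comparison, not per tract
  pair. Confidence intervals use a block bootstrap over individuals.
* **F_ST** uses pooled-frequency H_T and the unweighted mean of the two
  groups' heterozygosities, averaged over sites before the ratio;
  negative values are reported as such.
* **Tract-length regression** bins AI tract lengths into 10
  logarithmically spaced bins from 1 cM-equivalent (1 Mb at 1 cM/Mb) to
  the longest observed tract; each decade's proportions are normalized
  to 1, empty cells receive half the smallest positive proportion
  before the log, and the proportions are renormalized. Bins and
  decades enter as ordinal codes 0, 1, 2, ...
* **ROH × tract overlap** needs a diploid rule because ROH are unphased
  intervals while tracts are per-haplotype. The default (`"both"`)
  counts a base as ancestry-k-overlapping only when both haplotypes
  carry k there — an ROH implies locally identical haplotypes, so
  demanding homozygous ancestry is the self-consistent reading. The
  `"mean"` rule (average of the two haplotypes' indicators) is exposed;
  under it, and only under it, the per-size-class overlaps are exactly
  additive across ancestries when tracts tile the genome.
* **ROH size classes**: fixed boundaries 845,097 / 2,501,750 bp by
  default; `fit_class_boundaries()` refits a three-component
  unequal-variance Gaussian mixture on raw bp lengths (log-length mode
  available) and places boundaries at posterior-responsibility
  crossovers between adjacent component means, root-found on the fitted
  densities. Trend tests use Kendall's τ-b with asymptotic p.
* **Admixture mapping** regresses age (a fixed synthetic assessment
  year, 2008, minus birth year) on local-ancestry dosage with global AI
  ancestry, log sampling weight and center as covariates; the sign of
  interest (younger individuals carrying more AI ancestry) is a
  *negative* dosage effect on age. The logistic variant splits the
  cohort at birth year 1965. The genome-wide threshold divides alpha by
  an effective number of ancestral blocks: per individual and
  chromosome, the dosage sequence's effective sample size is
  `n * var / spec0` with `spec0` the spectral density at zero of an
  AIC-selected autoregressive fit (order ≤ 10); individual values are
  averaged (median exposed) and summed over chromosomes. How to
  aggregate across individuals is genuinely underdetermined; the mean is
  the default and the choice is configurable.
* **Polygenic score**: windows of 1 Mb are tiled from position 0 on each
  chromosome (the anchor is underdetermined; tiling from 0 is the
  simplest reproducible choice), the lowest-p genome-wide-significant
  SNP per window is kept (ties to the lowest position), and scores are
  dosage-weighted effect sums with mean imputation for missing dosages.
  Ancestry quartiles use the cohort's empirical 25/50/75 percentiles
  with right-closed intervals, so an individual exactly on an edge falls
  in the lower quartile.
* **Singular designs**: regression fits drop covariates that collapse
  to a single value or level in a fitted subset (small strata), and
  internal harness fits may drop aliased nuisance covariates; any other
  rank deficiency — in particular one involving the predictor of
  interest — raises an explicit singularity error.

## Problem sizes

The default test and pipeline scales are chosen for seconds-scale
iteration on one core: a 4 × 50 Mb genome at 1 cM/Mb with 2000 sites,
cohorts of tens to a few hundred individuals for tract-level analyses,
and the full n = 3622 only for cohort-table regressions (which are
cheap). Simulator checks run the stated N = 1000 population for 2N
steps across 50–100 replicates. The genome-concordance check, whose
precision is limited by total genetic length, uses a human-scale 22 ×
130 Mb map. None of these sizes is load-bearing for correctness; the
oracle-equivalence tests run at tiny sizes where brute force is exact.

## Known limitations

* The simulator's heritable quantity is the ancestry proportion itself;
  there is no sequence, no linkage, and therefore no within-genome
  heterogeneity of ancestry change. Questions about specific loci live
  in the admixture-mapping module, not the simulator.
* The generator's independence assumptions (sites, individuals) make
  type-I-error and recovery checks clean but understate the correlation
  structure of real data; passing them demonstrates correctness of the
  statistics, not robustness to LD or cryptic relatedness.
* Migrant ancestry is Beta with mean `mAI`; the true functional form
  linking migration waves to ancestry is unknown and this is a stand-in.
* The effective-number-of-tests threshold depends on the synthetic
  block structure and is not comparable to thresholds computed on real
  local-ancestry panels.
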