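Package: admixdyn
Title: Admixture Dynamics, Ancestry-Tract Statistics and Polygenic Score
    Portability in Recently Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Moran-model simulation of genome-wide ancestry
    proportions under ancestry-based assortative mating, fecundity
    differences, migration and population growth, together with the
    statistical toolkit used to study temporal shifts of Amerindigenous
    ancestry in Mexican American cohorts: ancestry-trend regressions with
    survey sampling weights, bootstrap-LOESS envelopes, nucleotide
    diversity and F_ST within local-ancestry tracts, tract-length
    distribution regression, runs-of-homozygosity size classification and
    ancestry overlap trends, admixture mapping with an
    autoregression-based effective-number-of-tests threshold, and
    polygenic height score construction with ancestry-stratified
    portability evaluation. A synthetic-cohort generator emulating the
    study design (birth years, sampling weights, three-way global
    ancestry, phased local-ancestry tracts, tract-resident genotypes, ROH
    and GWAS summary statistics) makes every analysis testable without
    access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mclust,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
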