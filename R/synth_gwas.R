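#' Generate synthetic GWAS summary statistics for a height-like trait
#'
#' Emulates summary statistics from a large external (European-ancestry)
#' GWAS over the panel sites: `n_causal` sites receive true effects drawn
#' from N(0, `effect_sd`); the reported effect is the true effect plus
#' estimation noise with standard error `1/sqrt(2 p (1-p) n_gwas)` at the
#' European panel frequency, and the p-value is the two-sided Wald p,
#' floored at `p_floor`. The true effect table is returned alongside so
#' polygenic-score validity is checkable against generating truth.
#'
#' @param freqs An [ancestry_panel_freqs()] table (provides sites and
#'   European panel frequencies).
#' @param n_causal Number of causal sites (>= 0).
#' @param effect_sd Sd of true causal effects (phenotype units per
#'   allele).
#' @param n_gwas Effective sample size of the emulated GWAS.
#' @param p_floor Smallest reportable p-value.
#' @param seed Integer seed.
#' @return A list: `summary` (a `gwas_summary` data.frame with `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `beta`, `se`, `p`) and `effects`
#'   (`snp_id`, `beta_true`, nonzero only at causal sites).
#' @export
generate_gwas_summary <- function(freqs, n_causal = 50, effect_sd = 0.5,
                                  n_gwas = 3.6e5, p_floor = 1e-300, seed = 1) {
  if (n_causal < 0) config_error("n_causal must be nonnegative")
  if (n_causal > nrow(freqs)) config_error("n_causal exceeds the number of sites")
  set.seed(seed)
  m <- nrow(freqs)
  beta_true <- numeric(m)
  if (n_causal > 0) {
    causal <- sample.int(m, n_causal)
    beta_true[causal] <- stats::rnorm(n_causal, 0, effect_sd)
  }
  p_eur <- clip(freqs$p_eur, 0.01, 0.99)
  se <- 1 / sqrt(2 * p_eur * (1 - p_eur) * n_gwas)
  beta_hat <- beta_true + stats::rnorm(m, 0, se)
  pval <- pmax(p_floor, 2 * stats::pnorm(-abs(beta_hat) / se))
  summ <- data.frame(
    snp_id = freqs$snp_id, chrom = freqs$chrom, pos = freqs$pos,
    effect_allele = "T", beta = beta_hat, se = se, p = pval,
    stringsAsFactors = FALSE
  )
  class(summ) <- c("gwas_summary", "data.frame")
  list(summary = summ,
       effects = data.frame(snp_id = freqs$snp_id, beta_true = beta_true,
                            stringsAsFactors = FALSE))
}

#' Attach a genetically informed height phenotype to a cohort
#'
#' Rebuilds the cohort's height as genetic value (true effects times
#' dosages) plus the configured ancestry effect, birth-year secular trend,
#' gender effect and Gaussian noise. Coefficients default to the cohort
#' config used at generation time.
#'
#' @param cohort A cohort data.frame.
#' @param geno A `hap_genotypes` object covering the cohort individuals.
#' @param effects The `effects` table from [generate_gwas_summary()].
#' @param config A [cohort_config()]; defaults to the one attached to
#'   `cohort`.
#' @param ai_attenuation Portability attenuation in \[0,1\]: the genetic
#'   value's contribution to height is scaled by
#'   `1 - ai_attenuation * anc_ai`, emulating the decay of European-GWAS
#'   effect sizes on increasingly Amerindigenous haplotype backgrounds
#'   (0 = fully portable effects).
#' @param seed Integer seed for the residual noise.
#' @return The cohort with `height` replaced and a `genetic_value` column
#'   added.
#' @export
attach_height <- function(cohort, geno, effects,
                          config = attr(cohort, "config"),
                          ai_attenuation = 0, seed = 1) {
  if (ai_attenuation < 0 || ai_attenuation > 1) {
    config_error("ai_attenuation must be in [0,1]")
  }
  stopifnot(inherits(geno, "hap_genotypes"))
  if (is.null(config)) config_error("no cohort_config available")
  set.seed(seed)
  dos <- dosage_matrix(geno)
  stopifnot(all(cohort$individual_id %in% rownames(dos)))
  b <- effects$beta_true[match(colnames(dos), effects$snp_id)]
  b[is.na(b)] <- 0
  gv <- as.numeric(dos[cohort$individual_id, , drop = FALSE] %*% b)
  gv <- gv - mean(gv)
  by_mid <- mean(config$birth_range)
  mu <- clip(config$mean_ai + config$slope_ai_per_year *
               (cohort$birth_year - by_mid), 0.01, 0.99)
  cohort$genetic_value <- gv
  cohort$height <- config$height_base +
    gv * (1 - ai_attenuation * cohort$anc_ai) +
    config$height_by_slope * (cohort$birth_year - by_mid) +
    config$height_female * (cohort$gender == "female") +
    config$height_ai_effect * (cohort$anc_ai - mu) +
    stats::rnorm(nrow(cohort), 0, config$height_sd)
  cohort
}
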