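#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the Mexican American arm of a large
#' US Hispanic/Latino community health cohort: n = 3622 individuals with
#' birth years 1934-1993, mean AI ancestry 0.489 rising by 0.0023 per birth
#' year, four recruitment centers dominated by San Diego and Chicago,
#' about 17.5% US-born, survey sampling weights entering analyses on the
#' log scale, and a height phenotype with a secular trend of 0.096 cm per
#' birth year.
#'
#' @param n Number of individuals (>= 2).
#' @param mean_ai Mean AI ancestry proportion at the midpoint birth year.
#' @param slope_ai_per_year Linear birth-year effect on the mean AI
#'   ancestry (ancestry proportion per year).
#' @param birth_range Inclusive birth-year range; years drawn uniformly.
#' @param ai_concentration Beta concentration of individual AI ancestry
#'   around its birth-year mean (default 8, i.e. sd about 0.17, a
#'   realistic dispersion of AI ancestry for Mexican American cohorts).
#' @param afr_mean,afr_concentration Mean/concentration of the African
#'   share of the non-AI remainder.
#' @param weight_meanlog,weight_sdlog Log-normal sampling-weight
#'   parameters.
#' @param weight_by_corr Correlation between log sampling weight and birth
#'   year (negative mimics oversampling of older residents).
#' @param p_female Probability of gender "female".
#' @param center_probs Named recruitment-center probabilities.
#' @param p_us_born Probability of being US-born.
#' @param us_parent_probs Probabilities of 0/1/2 US-born parents among the
#'   US-born.
#' @param edu_probs Probabilities of educational attainment `<HS`, `=HS`,
#'   `>HS`.
#' @param years_in_us_effect Effect of years in the US on AI ancestry for
#'   non-US-born individuals (default 0; the ancestry-biased-migration
#'   analyses switch it on).
#' @param parental_r Target correlation between the two parents' AI
#'   ancestries.
#' @param height_base Mean male height (cm) at the midpoint birth year.
#' @param height_female Additive height effect of gender "female" (cm).
#' @param height_by_slope Secular height trend (cm per birth year).
#' @param height_ai_effect Height effect (cm) per unit AI ancestry, applied
#'   to the ancestry residual about its birth-year mean so the secular
#'   trend coefficient stays interpretable as the total birth-year effect.
#' @param height_sd Residual height sd (cm).
#' @return A validated `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n = 200, seed_check = FALSE)
cohort_config <- function(n = 3622,
                          mean_ai = 0.489,
                          slope_ai_per_year = 0.0023,
                          birth_range = c(1934, 1993),
                          ai_concentration = 8,
                          afr_mean = 0.08, afr_concentration = 30,
                          weight_meanlog = 0, weight_sdlog = 0.5,
                          weight_by_corr = -0.3,
                          p_female = 0.586,
                          center_probs = c("San Diego" = 0.597,
                                           "Chicago" = 0.362,
                                           "Bronx" = 0.034,
                                           "Miami" = 0.007),
                          p_us_born = 0.175,
                          us_parent_probs = c(0.607, 0.235, 0.158),
                          edu_probs = c("<HS" = 0.420, "=HS" = 0.265,
                                        ">HS" = 0.315),
                          years_in_us_effect = 0,
                          parental_r = 0.708,
                          height_base = 167,
                          height_female = -12.5,
                          height_by_slope = 0.096,
                          height_ai_effect = -10,
                          height_sd = 6.5,
                          seed_check = TRUE) {
  if (!is.numeric(n) || n < 2) config_error("n must be at least 2")
  if (mean_ai <= 0 || mean_ai >= 1) config_error("mean_ai must be in (0,1)")
  if (length(birth_range) != 2 || diff(birth_range) <= 0) {
    config_error("birth_range must be an increasing pair of years")
  }
  if (ai_concentration <= 0) config_error("ai_concentration must be positive")
  # refuse configurations where the linear mean escapes [0.01, 0.99] over
  # more than half the birth-year range: the clipped trend would no longer
  # be the configured one
  if (seed_check && slope_ai_per_year != 0) {
    yrs <- seq(birth_range[1], birth_range[2], by = 1)
    mu_lin <- mean_ai + slope_ai_per_year * (yrs - mean(birth_range))
    if (mean(mu_lin < 0.01 | mu_lin > 0.99) > 0.5) {
      config_error("slope_ai_per_year pushes most of the birth-year range outside [0.01, 0.99]")
    }
  }
  if (abs(weight_by_corr) >= 1) config_error("weight_by_corr must be in (-1,1)")
  if (abs(sum(center_probs) - 1) > 1e-6 || any(center_probs < 0)) {
    config_error("center_probs must be nonnegative and sum to 1")
  }
  if (abs(sum(us_parent_probs) - 1) > 1e-6) {
    config_error("us_parent_probs must sum to 1")
  }
  if (abs(sum(edu_probs) - 1) > 1e-6) config_error("edu_probs must sum to 1")
  if (parental_r <= -1 || parental_r >= 1) config_error("parental_r must be in (-1,1)")
  cfg <- as.list(environment())
  cfg$half <- NULL; cfg$lin_lo <- NULL; cfg$lin_hi <- NULL; cfg$seed_check <- NULL
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort table
#'
#' Produces one row per individual with birth year, gender, recruitment
#' center, sampling weight, educational attainment, US-born status and
#' number of US-born parents (US-born only), years in the US (non-US-born
#' only), three-way global ancestry proportions summing exactly to 1,
#' "true" parental AI ancestries with the configured parental correlation,
#' and a height phenotype carrying a secular birth-year trend, a gender
#' effect and an AI-ancestry effect.
#'
#' The individual AI ancestry is Beta distributed around a linear-in-birth-
#' year mean (clipped to \[0.01, 0.99\]), so an OLS regression of ancestry
#' on birth year plus log sampling weight recovers
#' `slope_ai_per_year` in expectation.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed.
#' @return A `cohort` data.frame.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 500), seed = 1)
#' coef(lm(anc_ai ~ birth_year + log(sampling_weight), data = coh))
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- as.integer(config$n)
  by_mid <- mean(config$birth_range)
  birth_year <- as.integer(round(stats::runif(n, config$birth_range[1] - 0.499,
                                              config$birth_range[2] + 0.499)))

  # survey weight: log-normal, correlated with birth year via a Gaussian copula
  z_by <- (birth_year - by_mid) / stats::sd(birth_year)
  z_w <- config$weight_by_corr * z_by +
    sqrt(1 - config$weight_by_corr^2) * stats::rnorm(n)
  sampling_weight <- exp(config$weight_meanlog + config$weight_sdlog * z_w)

  gender <- factor(ifelse(stats::runif(n) < config$p_female, "female", "male"),
                   levels = c("female", "male"))
  center <- factor(sample(names(config$center_probs), n, replace = TRUE,
                          prob = config$center_probs),
                   levels = names(config$center_probs))
  education <- factor(sample(names(config$edu_probs), n, replace = TRUE,
                             prob = config$edu_probs),
                      levels = names(config$edu_probs))
  us_born <- stats::runif(n) < config$p_us_born
  n_us_born_parents <- ifelse(
    us_born,
    sample(0:2, n, replace = TRUE, prob = config$us_parent_probs),
    NA_integer_)
  # years in the US for the non-US-born: anywhere from recent arrival to
  # essentially a lifetime ago, bounded by age at a fixed assessment year
  assess <- attr(config, "assessment_year") %||% 2008
  age <- assess - birth_year
  years_in_us <- ifelse(us_born, NA_real_,
                        stats::runif(n, 1, pmax(2, age - 1)))

  # AI ancestry: Beta around a linear-in-birth-year mean
  mu <- clip(config$mean_ai + config$slope_ai_per_year * (birth_year - by_mid),
             0.01, 0.99)
  if (config$years_in_us_effect != 0) {
    yc <- ifelse(us_born, 0, years_in_us - mean(years_in_us, na.rm = TRUE))
    mu <- clip(mu + config$years_in_us_effect * yc, 0.01, 0.99)
  }
  if (stats::sd(mu) == 0 && config$slope_ai_per_year != 0) {
    config_error("configured slope is entirely clipped away; no trend left to recover")
  }
  v <- config$ai_concentration
  anc_ai <- if (is.finite(v)) stats::rbeta(n, mu * v, (1 - mu) * v) else mu
  # numerical floor: keep proportions off the exact boundary
  anc_ai <- clip(anc_ai, 1e-6, 1 - 1e-6)
  afr_frac <- rbeta_mc(n, config$afr_mean, config$afr_concentration)
  anc_afr <- (1 - anc_ai) * afr_frac
  anc_eur <- 1 - anc_ai - anc_afr

  # parental AI ancestry: symmetric construction around the offspring value
  # with within-pair spread tuned to the target parental correlation
  sd_a <- max(stats::sd(anc_ai), 1e-12)
  sd_d <- sd_a * sqrt((1 - config$parental_r) / (1 + config$parental_r))
  d <- stats::rnorm(n, 0, sd_d)
  parent1_ai <- clip(anc_ai + d)
  parent2_ai <- clip(anc_ai - d)

  # height: secular trend + gender + AI effect on the ancestry residual
  anc_resid <- anc_ai - mu
  height <- config$height_base +
    config$height_by_slope * (birth_year - by_mid) +
    config$height_female * (gender == "female") +
    config$height_ai_effect * anc_resid +
    stats::rnorm(n, 0, config$height_sd)

  coh <- data.frame(
    individual_id = sprintf("ind%05d", seq_len(n)),
    birth_year = birth_year,
    gender = gender,
    center = center,
    sampling_weight = sampling_weight,
    education = education,
    us_born = us_born,
    n_us_born_parents = n_us_born_parents,
    years_in_us = years_in_us,
    anc_afr = anc_afr,
    anc_eur = anc_eur,
    anc_ai = anc_ai,
    parent1_ai = parent1_ai,
    parent2_ai = parent2_ai,
    height = height,
    stringsAsFactors = FALSE
  )
  attr(coh, "config") <- config
  class(coh) <- c("cohort", "data.frame")
  coh
}

#' Validate cohort invariants
#'
#' Checks that ancestry proportions sum to 1 within 1e-9, birth years lie
#' in the configured range, sampling weights are positive, and
#' `n_us_born_parents` is defined exactly for the US-born.
#'
#' @param cohort A cohort data.frame.
#' @return Invisibly `TRUE`; otherwise a structural error.
#' @export
validate_cohort <- function(cohort) {
  req <- c("individual_id", "birth_year", "sampling_weight",
           "anc_afr", "anc_eur", "anc_ai")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) structural_error(paste("cohort lacks columns:",
                                           paste(miss, collapse = ", ")))
  s <- cohort$anc_afr + cohort$anc_eur + cohort$anc_ai
  if (any(abs(s - 1) > 1e-9)) structural_error("ancestry proportions do not sum to 1")
  if (any(cohort$sampling_weight <= 0)) structural_error("sampling weights must be positive")
  if (all(c("us_born", "n_us_born_parents") %in% names(cohort))) {
    if (any(!is.na(cohort$n_us_born_parents) & !cohort$us_born)) {
      structural_error("n_us_born_parents defined for non-US-born individuals")
    }
  }
  invisible(TRUE)
}
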