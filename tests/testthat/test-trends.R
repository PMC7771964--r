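# Trend regressions, bootstrap-LOESS, quantile normalization, trait
# harness, parental correlation.

test_that("the OLS engine matches the normal-equations oracle", {
  set.seed(1)
  for (k in 1:25) {
    n <- sample(30:120, 1)
    coh <- data.frame(
      individual_id = seq_len(n),
      birth_year = sample(1934:1993, n, replace = TRUE),
      sampling_weight = rlnorm(n),
      anc_ai = runif(n), extra = rnorm(n)
    )
    coh$anc_ai <- coh$anc_ai + 0.001 * coh$birth_year + 0.1 * coh$extra
    ft <- fit_trend(coh, extra_covariates = "extra")
    X <- cbind(1, coh$birth_year, log(coh$sampling_weight), coh$extra)
    expect_equal(unname(ft$coefficients$estimate),
                 ols_oracle(X, coh$anc_ai), tolerance = 1e-8)
  }
})

test_that("a noiseless zero-slope cohort fits a flat line exactly", {
  coh <- generate_cohort(cohort_config(n = 120, slope_ai_per_year = 0,
                                       ai_concentration = Inf), seed = 2)
  ft <- fit_trend(coh)
  expect_lt(abs(birth_year_effect(ft)[["estimate"]]), 1e-12)
})

test_that("stratified trends fit each level and apply the Bonferroni rule", {
  coh <- generate_cohort(cohort_config(n = 1200), seed = 3)
  out <- stratified_trends(coh, "gender")
  expect_identical(nrow(out), 2L)
  expect_false(any(out$skipped))

  # a single-level stratum reduces to the plain fit
  coh$one <- factor("only")
  out1 <- stratified_trends(coh, "one")
  ft <- fit_trend(coh)
  expect_equal(out1$estimate, unname(birth_year_effect(ft)[["estimate"]]))

  # the study's convention: nine stratified tests
  out9 <- stratified_trends(coh, "gender", n_tests = 9)
  expect_equal(attr(out9, "threshold"), 0.05 / 9)

  # tiny strata are skipped with a warning
  coh$tiny <- factor(c("rare", rep("common", nrow(coh) - 1)))
  expect_warning(outt <- stratified_trends(coh, "tiny"), "skipped")
  expect_true(outt$skipped[outt$stratum == "rare"])
})

test_that("the years-in-US model separates migration timing from the trend", {
  ests <- t(vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(n = 3000,
                                         years_in_us_effect = -0.0009),
                           seed = s)
    ft <- years_in_us_model(coh)
    c(by = ft$coefficients["birth_year", "estimate"],
      yrs = ft$coefficients["years_in_us", "estimate"])
  }, numeric(2)))
  expect_lt(abs(mean(ests[, "yrs"]) + 0.0009),
            3 * sd(ests[, "yrs"]) / sqrt(nrow(ests)))
  expect_lt(abs(mean(ests[, "by"]) - 0.0023),
            3 * sd(ests[, "by"]) / sqrt(nrow(ests)))

  # zero years effect is recovered as zero
  coh0 <- generate_cohort(cohort_config(n = 3000), seed = 99)
  ft0 <- years_in_us_model(coh0)
  ci <- ft0$coefficients["years_in_us", c("ci_lo", "ci_hi")]
  expect_true(ci$ci_lo < 0 && ci$ci_hi > 0)

  # exact collinearity raises the singularity error
  cohc <- generate_cohort(cohort_config(n = 200), seed = 5)
  cohc$years_in_us <- 2008 - cohc$birth_year
  expect_error(years_in_us_model(cohc), class = "admixdyn_singular_error")
})

test_that("the parental-birthplace interaction recovers baseline and offsets", {
  gen <- function(s) {
    set.seed(s)
    n <- 1500
    by <- sample(1934:1993, n, replace = TRUE)
    g <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    slopes <- c(0.004, 0.004 - 0.0034, 0.004 - 0.0049)
    anc <- 0.45 + slopes[g + 1] * (by - 1963.5) + rnorm(n, 0, 0.12)
    data.frame(individual_id = seq_len(n), birth_year = by,
               sampling_weight = rlnorm(n), anc_ai = pmin(pmax(anc, 0), 1),
               us_born = TRUE, n_us_born_parents = g)
  }
  ests <- t(vapply(1:30, function(s) interaction_slopes(
    parental_birthplace_interaction(gen(s))), numeric(3)))
  for (j in seq_len(3)) {
    truth <- c(0.004, -0.0034, -0.0049)[j]
    se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - truth), 3 * se)
  }
  # coefficients agree with an explicit design-matrix oracle
  coh <- gen(77)
  ft <- parental_birthplace_interaction(coh)
  pu <- factor(coh$n_us_born_parents, levels = 0:2)
  X <- model.matrix(~ birth_year * pu + log(sampling_weight), data = coh)
  oracle <- ols_oracle(X, coh$anc_ai)
  idx <- match(colnames(X), colnames(X)) # same ordering as lm
  expect_equal(sort(ft$coefficients$estimate), sort(oracle), tolerance = 1e-8)
})

test_that("bootstrap-LOESS envelopes behave like quantile bands", {
  coh <- generate_cohort(cohort_config(n = 300), seed = 6)
  # constant response: all curves identical, zero-width band
  cohc <- coh
  cohc$anc_ai <- 0.5
  envc <- bootstrap_loess(cohc, n_iter = 20, seed = 1)
  expect_lt(max(envc$upper - envc$lower), 1e-8)

  # the default iteration count retains exactly 1000 curves
  env <- bootstrap_loess(coh[1:80, ], seed = 2)
  expect_identical(nrow(env$curves), 1000L)
  expect_true(all(env$lower <= env$upper))

  # a linear generating truth lies inside the band at >= 90% of the grid
  cfg <- cohort_config(n = 400)
  cohl <- generate_cohort(cfg, seed = 7)
  envl <- bootstrap_loess(cohl, n_iter = 300, seed = 3)
  truth <- 0.489 + 0.0023 * (envl$grid - mean(cfg$birth_range))
  covered <- mean(truth >= envl$lower & truth <= envl$upper)
  expect_gte(covered, 0.9)

  # envelopes tighten as the cohort grows
  env_big <- bootstrap_loess(generate_cohort(cohort_config(n = 1600), seed = 8),
                             n_iter = 200, seed = 4)
  env_small <- bootstrap_loess(generate_cohort(cohort_config(n = 200), seed = 8),
                               n_iter = 200, seed = 4)
  expect_lt(mean(env_big$upper - env_big$lower),
            mean(env_small$upper - env_small$lower))

  expect_error(bootstrap_loess(coh, grid = c(1900, 1960)),
               class = "admixdyn_structural_error")
})

test_that("quantile normalization maps ranks onto standard-normal scores", {
  out <- quantile_normalize(c(30, 10, 20))
  expect_equal(out, qnorm(c(5 / 6, 1 / 6, 3 / 6)))
  expect_equal(out[1], 0.9674, tolerance = 1e-4)

  set.seed(9)
  x <- rnorm(500)
  qx <- quantile_normalize(x)
  expect_lt(abs(mean(qx)), 1e-9)
  expect_identical(order(qx), order(x))
  # idempotent on ranks
  expect_equal(quantile_normalize(qx), qx, tolerance = 1e-12)

  expect_error(quantile_normalize(1), class = "admixdyn_config_error")
  expect_error(quantile_normalize(rep(2, 5)), class = "admixdyn_config_error")
})

test_that("the trait harness reports calibrated null associations", {
  coh <- generate_cohort(cohort_config(n = 250), seed = 10)
  set.seed(10)
  n_null <- 400
  traits <- paste0("t", seq_len(n_null))
  for (tr in traits) coh[[tr]] <- rnorm(nrow(coh))
  out <- trait_association_harness(coh, traits)
  expect_equal(nrow(out), n_null)
  rate <- mean(out$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  expect_equal(attr(out, "threshold"), 0.05 / n_null)

  # a trait that IS ancestry: maximal signal, effect equal to the direct
  # covariate-adjusted regression of its normal scores on ancestry
  coh$self <- coh$anc_ai
  outs <- trait_association_harness(coh, "self")
  expect_lt(outs$p, 1e-100)
  expect_gt(outs$estimate, 0)
})

test_that("parental correlation comes with Fisher-z intervals", {
  set.seed(11)
  p1 <- runif(200)
  out <- parental_correlation(p1, p1)
  expect_equal(out$r, 1)
  p2 <- runif(200)
  out0 <- parental_correlation(p1, p2)
  expect_true(out0$ci_lo < 0 && out0$ci_hi > 0)
  expect_error(parental_correlation(rep(0.5, 10), runif(10)),
               class = "admixdyn_config_error")
  # decade-stratified variant returns one row per decade
  by <- sample(c(1940, 1950, 1960), 200, replace = TRUE)
  outd <- parental_correlation(p1, p1 + rnorm(200, 0, 0.1), by = by)
  expect_identical(nrow(outd), 3L)
})

test_that("group tests dispatch between t-test and ANOVA", {
  coh <- generate_cohort(cohort_config(n = 300), seed = 12)
  expect_s3_class(ancestry_group_test(coh, "gender"), "htest")
  expect_true(inherits(ancestry_group_test(coh, "education"),
                       "summary.aov"))
})
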