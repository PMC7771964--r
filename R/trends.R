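#' Fit the ancestry-trend regression
#'
#' Ordinary least squares of an ancestry proportion on birth year (BY) and
#' the natural log of the sampling weight (SW):
#' `Ancestry = b0 + b1 BY + b2 SW + e`, optionally with further
#' covariates. `b1` is the birth-year effect of interest.
#'
#' @param cohort A cohort data.frame.
#' @param response Response column (default `"anc_ai"`).
#' @param extra_covariates Character vector of additional covariate
#'   columns.
#' @param data_subset Optional logical vector selecting rows.
#' @return A `trend_fit` list: `coefficients` (data.frame with estimate,
#'   se, 95% CI, p), `r_squared`, `n`, `response`, and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 400), seed = 1)
#' fit_trend(coh)$coefficients["birth_year", ]
fit_trend <- function(cohort, response = "anc_ai", extra_covariates = character(0),
                      data_subset = NULL) {
  req <- c(response, "birth_year", "sampling_weight", extra_covariates)
  miss <- setdiff(req, names(cohort))
  if (length(miss)) structural_error(paste("missing columns:", paste(miss, collapse = ", ")))
  df <- as.data.frame(cohort)
  if (!is.null(data_subset)) df <- df[data_subset, , drop = FALSE]
  df$log_weight <- log(df$sampling_weight)
  vars <- c("birth_year", "log_weight", extra_covariates)
  df <- df[stats::complete.cases(df[c(response, vars)]), , drop = FALSE]
  fml <- stats::reformulate(vars, response = response)
  .ols_trend_fit(fml, df, response)
}

# shared OLS engine: fit, check rank, assemble the coefficient table.
# Covariates that collapse to a single value/level in the fitted subset
# (small strata) are dropped up front. When `droppable` names nuisance
# terms, those may additionally be removed if aliased (exactly collinear)
# and the model is refit; any other rank deficiency -- in particular one
# involving the term of interest -- raises the singularity error.
.ols_trend_fit <- function(fml, df, response, droppable = character(0)) {
  tl <- attr(stats::terms(fml), "term.labels")
  vars <- all.vars(fml)[-1]
  degenerate <- vars[vapply(vars, function(v) {
    length(unique(df[[v]][!is.na(df[[v]])])) < 2
  }, logical(1))]
  if (length(degenerate)) {
    keep <- tl[!vapply(tl, function(t) {
      any(all.vars(stats::reformulate(t)) %in% degenerate)
    }, logical(1))]
    if (!length(keep)) stop("no usable covariates left")
    fml <- stats::reformulate(keep, response = fml[[2]])
  }
  df <- droplevels(df)
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit)) && length(droppable)) {
    tl2 <- attr(stats::terms(fit), "term.labels")
    aliased <- unique(fit$assign[is.na(stats::coef(fit))])
    aliased <- aliased[aliased > 0]
    bad_terms <- tl2[aliased]
    if (all(bad_terms %in% droppable)) {
      fml <- stats::reformulate(setdiff(tl2, bad_terms), response = fml[[2]])
      fit <- stats::lm(fml, data = df)
    }
  }
  if (anyNA(stats::coef(fit))) {
    stop(errorCondition("singular design: a covariate is collinear",
                        class = c("admixdyn_singular_error", "error")))
  }
  # noiseless generators yield exact fits; the perfect-fit warning from
  # summary.lm is expected there
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  ci <- suppressWarnings(stats::confint(fit))
  tab <- data.frame(estimate = cf[, 1], se = cf[, 2],
                    ci_lo = ci[, 1], ci_hi = ci[, 2], p = cf[, 4])
  out <- list(coefficients = tab, r_squared = sm$r.squared,
              n = length(stats::resid(fit)), response = response, fit = fit)
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Trend fit:", x$response, " (n =", x$n,
      ", R^2 =", signif(x$r_squared, 3), ")\n")
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}

#' Birth-year coefficient of a trend fit
#' @param fit A `trend_fit`.
#' @return Named numeric: estimate, se, ci_lo, ci_hi, p.
#' @export
birth_year_effect <- function(fit) {
  unlist(fit$coefficients["birth_year", ])
}

#' Stratified ancestry-trend regressions
#'
#' Fits [fit_trend()] within each level of a stratifying column and flags
#' significance at the Bonferroni level `alpha / n_tests` (default
#' `n_tests` = number of strata actually fitted; the study's convention
#' with 9 stratified tests gives 0.05/9 ~ 0.006).
#'
#' @param cohort A cohort data.frame.
#' @param stratum Name of a categorical column.
#' @param response Response column.
#' @param alpha Family-wise error target (default 0.05).
#' @param n_tests Bonferroni divisor override.
#' @return A data.frame, one row per stratum: `stratum`, `n`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, `p`, `significant`, `skipped`.
#' @export
stratified_trends <- function(cohort, stratum, response = "anc_ai",
                              alpha = 0.05, n_tests = NULL) {
  if (!stratum %in% names(cohort)) structural_error("stratum column not found")
  levs <- if (is.factor(cohort[[stratum]])) levels(droplevels(cohort[[stratum]]))
          else sort(unique(cohort[[stratum]]))
  rows <- vector("list", length(levs))
  for (i in seq_along(levs)) {
    sel <- cohort[[stratum]] == levs[i]
    n_i <- sum(sel, na.rm = TRUE)
    if (n_i < 4) {
      warning("stratum '", levs[i], "' too small (n = ", n_i, "); skipped")
      rows[[i]] <- data.frame(stratum = as.character(levs[i]), n = n_i,
                              estimate = NA_real_, se = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                              skipped = TRUE)
      next
    }
    ft <- fit_trend(cohort, response = response, data_subset = which(sel))
    be <- birth_year_effect(ft)
    rows[[i]] <- data.frame(stratum = as.character(levs[i]), n = ft$n,
                            estimate = be[["estimate"]], se = be[["se"]],
                            ci_lo = be[["ci_lo"]], ci_hi = be[["ci_hi"]],
                            p = be[["p"]], skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  k <- n_tests %||% sum(!out$skipped)
  out$significant <- !out$skipped & out$p < alpha / max(1, k)
  attr(out, "threshold") <- alpha / max(1, k)
  rownames(out) <- NULL
  out
}

#' Ancestry trend adjusting for years lived in the US
#'
#' Restricted to non-US-born individuals; fits
#' `anc_ai ~ birth_year + years_in_us + log(sampling_weight)` to separate
#' the birth-year trend from ancestry-biased migration timing.
#'
#' @param cohort A cohort data.frame with `us_born` and `years_in_us`.
#' @param response Response column.
#' @return A `trend_fit`.
#' @export
years_in_us_model <- function(cohort, response = "anc_ai") {
  if (!all(c("us_born", "years_in_us") %in% names(cohort))) {
    structural_error("cohort lacks us_born/years_in_us")
  }
  fit_trend(cohort, response = response, extra_covariates = "years_in_us",
            data_subset = which(!cohort$us_born))
}

#' Birth-year by parental-birthplace interaction model
#'
#' Restricted to US-born individuals; fits the ancestry trend with an
#' interaction between birth year and the number of US-born parents
#' (0/1/2 as a factor, baseline 0). The reported interaction terms are the
#' slope offsets that add to the baseline birth-year effect.
#'
#' @param cohort A cohort data.frame.
#' @param response Response column.
#' @return A `trend_fit`; the helper [interaction_slopes()] extracts the
#'   baseline slope and the per-group offsets.
#' @export
parental_birthplace_interaction <- function(cohort, response = "anc_ai") {
  if (!all(c("us_born", "n_us_born_parents") %in% names(cohort))) {
    structural_error("cohort lacks us_born/n_us_born_parents")
  }
  df <- as.data.frame(cohort)[cohort$us_born, , drop = FALSE]
  if (!all(df$n_us_born_parents %in% 0:2)) {
    structural_error("n_us_born_parents must be 0, 1 or 2 for US-born individuals")
  }
  df$log_weight <- log(df$sampling_weight)
  df$parents_us <- factor(df$n_us_born_parents, levels = 0:2)
  df <- df[stats::complete.cases(df[c(response, "birth_year", "log_weight",
                                      "parents_us")]), , drop = FALSE]
  fml <- stats::as.formula(paste(response,
                                 "~ birth_year * parents_us + log_weight"))
  .ols_trend_fit(fml, df, response)
}

#' Baseline slope and interaction offsets of the parental-birthplace model
#' @param fit A `trend_fit` from [parental_birthplace_interaction()].
#' @return Named numeric: `baseline`, `offset_1`, `offset_2`.
#' @export
interaction_slopes <- function(fit) {
  cf <- fit$coefficients$estimate
  names(cf) <- rownames(fit$coefficients)
  c(baseline = unname(cf["birth_year"]),
    offset_1 = unname(cf["birth_year:parents_us1"]),
    offset_2 = unname(cf["birth_year:parents_us2"]))
}

#' Bootstrap-LOESS envelope of an ancestry trend
#'
#' Resamples individuals with replacement `n_iter` times, fits a LOESS
#' smooth of the response on birth year for each resample, evaluates every
#' curve on a common birth-year grid, and returns the pointwise 2.5%/97.5%
#' quantile band.
#'
#' @param cohort A cohort data.frame.
#' @param response Response column.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param span LOESS span in (0, 1\].
#' @param grid Evaluation grid (defaults to 51 points over the observed
#'   birth-year range). Grid points outside the data range are an error.
#' @param seed Integer seed.
#' @return A `loess_envelope` list: `grid`, `curves` (n_iter x grid
#'   matrix), `lower`, `upper`, `median`, `n_iter`.
#' @export
bootstrap_loess <- function(cohort, response = "anc_ai", n_iter = 1000,
                            span = 0.75, grid = NULL, seed = 1) {
  if (n_iter < 1) config_error("n_iter must be at least 1")
  if (span <= 0 || span > 1) config_error("span must be in (0, 1]")
  by <- cohort$birth_year
  y <- cohort[[response]]
  grid <- grid %||% seq(min(by), max(by), length.out = 51)
  if (min(grid) < min(by) || max(grid) > max(by)) {
    structural_error("grid extends beyond the observed birth-year range")
  }
  set.seed(seed)
  n <- length(y)
  curves <- matrix(NA_real_, nrow = n_iter, ncol = length(grid))
  for (b in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    dd <- data.frame(by = by[idx], y = y[idx])
    # a resample can shrink the covariate range below the grid; the direct
    # surface lets predict() evaluate the local fit there instead of NA
    lo <- suppressWarnings(stats::loess(y ~ by, data = dd, span = span,
                                        degree = 2,
                                        control = stats::loess.control(
                                          surface = "direct")))
    curves[b, ] <- stats::predict(lo, data.frame(by = grid))
  }
  out <- list(grid = grid, curves = curves,
              lower = apply(curves, 2, stats::quantile, 0.025, na.rm = TRUE),
              upper = apply(curves, 2, stats::quantile, 0.975, na.rm = TRUE),
              median = apply(curves, 2, stats::median, na.rm = TRUE),
              n_iter = n_iter, span = span)
  class(out) <- "loess_envelope"
  out
}

#' Rank-based inverse-normal (quantile) normalization
#'
#' Maps values to `qnorm((rank - 0.5)/n)`, forcing the empirical
#' distribution to standard normal while preserving rank order. Ties get
#' average ranks.
#'
#' @param x Numeric vector, `n >= 2`, not all tied.
#' @return Normalized numeric vector.
#' @export
#' @examples
#' quantile_normalize(c(3, 1, 2))
quantile_normalize <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) config_error("quantile normalization needs at least 2 values")
  if (length(unique(x[!is.na(x)])) < 2) {
    config_error("all values tied: quantile normalization undefined")
  }
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm((r - 0.5) / sum(!is.na(x)))
}

#' Association of global AI ancestry with a set of traits
#'
#' For each trait: quantile-normalize, regress on AI ancestry plus the
#' covariate set (birth year, center, gender, log sampling weight,
#' education, US-born status, number of US-born parents -- with 0 imputed
#' for the non-US-born, whose parents are US-born only exceptionally), and
#' report the AI effect with a Bonferroni threshold of
#' `alpha / n_tests` (default `n_tests` = number of traits).
#'
#' @param cohort A cohort data.frame.
#' @param traits Character vector of trait columns.
#' @param covariates Covariate columns (log sampling weight is derived
#'   automatically from `sampling_weight`).
#' @param alpha Family-wise error target.
#' @param n_tests Bonferroni divisor override (the study's printed
#'   threshold corresponds to a larger genome-wide test count).
#' @return A data.frame: `trait`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `p`, `significant`; threshold in `attr(, "threshold")`.
#' @export
trait_association_harness <- function(cohort, traits,
                                      covariates = c("birth_year", "center",
                                                     "gender", "log_weight",
                                                     "education", "us_born",
                                                     "n_us_born_parents0"),
                                      alpha = 0.05, n_tests = NULL) {
  if (length(traits) < 1) config_error("at least one trait required")
  df <- as.data.frame(cohort)
  df$log_weight <- log(df$sampling_weight)
  df$n_us_born_parents0 <- ifelse(df$us_born, df$n_us_born_parents, 0L)
  covariates <- intersect(covariates, names(df))
  rows <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    tr <- traits[i]
    y <- quantile_normalize(df[[tr]])
    dd <- df
    dd$.qn_trait <- y
    fml <- stats::reformulate(c("anc_ai", covariates), response = ".qn_trait")
    ft <- .ols_trend_fit(fml, dd, tr, droppable = covariates)
    cf <- ft$coefficients["anc_ai", ]
    rows[[i]] <- data.frame(trait = tr, estimate = cf$estimate, se = cf$se,
                            ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, p = cf$p)
  }
  out <- do.call(rbind, rows)
  k <- n_tests %||% length(traits)
  out$significant <- out$p < alpha / k
  attr(out, "threshold") <- alpha / k
  rownames(out) <- NULL
  out
}

#' Pearson correlation of parental ancestries
#'
#' Pearson r of the two parents' AI ancestry proportions with a Fisher-z
#' 95% confidence interval; optionally stratified (e.g. by birth decade).
#'
#' @param parent1_ai,parent2_ai Numeric vectors (>= 3 pairs).
#' @param by Optional grouping vector for a stratified variant.
#' @return A data.frame with `group` (or `"all"`), `n`, `r`, `ci_lo`,
#'   `ci_hi`, `p`.
#' @export
parental_correlation <- function(parent1_ai, parent2_ai, by = NULL) {
  one <- function(p1, p2, label) {
    if (length(p1) < 3) config_error("need at least 3 parent pairs")
    if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
      config_error("zero variance: correlation undefined")
    }
    ct <- stats::cor.test(p1, p2, method = "pearson")
    data.frame(group = label, n = length(p1), r = unname(ct$estimate),
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(parent1_ai, parent2_ai, "all"))
  sp <- split(seq_along(parent1_ai), by)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    one(parent1_ai[sp[[g]]], parent2_ai[sp[[g]]], g)
  }))
  rownames(out) <- NULL
  out
}

#' Group-difference tests for ancestry (t-test / one-way ANOVA)
#'
#' Thin utility: Welch t-test for two groups, one-way ANOVA otherwise.
#'
#' @param cohort A cohort data.frame.
#' @param group Grouping column name.
#' @param response Response column.
#' @return The `htest`/`aov` summary object.
#' @export
ancestry_group_test <- function(cohort, group, response = "anc_ai") {
  g <- droplevels(factor(cohort[[group]]))
  y <- cohort[[response]]
  if (nlevels(g) < 2) config_error("need at least two groups")
  if (nlevels(g) == 2) {
    stats::t.test(y ~ g)
  } else {
    summary(stats::aov(y ~ g))
  }
}
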