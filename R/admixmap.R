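#' Local-ancestry dosage matrix
#'
#' Per individual and site, the number of haplotypes (0/1/2) whose
#' covering tract carries the target ancestry.
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param sites A data.frame with `chrom`, `pos` (and optionally
#'   `snp_id`), e.g. the `sites` table of a `hap_genotypes` object or an
#'   [ancestry_panel_freqs()] table.
#' @param label Target ancestry (default `"AI"`).
#' @return Integer matrix (individual x site).
#' @export
ancestry_dosage <- function(tracts, sites, label = "AI") {
  lab <- tract_labels_at_sites(tracts, sites)
  if (anyNA(lab)) structural_error("a site is not covered by any tract")
  ind <- unique(sub("\\|[01]$", "", rownames(lab)))
  d <- (lab[paste0(ind, "|0"), , drop = FALSE] == label) +
    (lab[paste0(ind, "|1"), , drop = FALSE] == label)
  rownames(d) <- ind
  storage.mode(d) <- "integer"
  d
}

# covariate design shared by the two admixture-mapping scans:
# global AI ancestry, log sampling weight, recruitment center
.admixmap_design <- function(cohort) {
  stats::model.matrix(~ anc_ai + log(sampling_weight) + center,
                      data = as.data.frame(cohort))
}

#' Admixture-mapping linear scan
#'
#' Per site, OLS of age (a fixed assessment year minus birth year) on the
#' local-ancestry dosage, adjusting for global AI ancestry, log sampling
#' weight and recruitment center. A positive dosage effect on age means
#' OLDER individuals carry more target ancestry at the site; the study's
#' direction of interest (younger individuals carrying excess ancestry)
#' is a negative effect on age.
#'
#' @param dosage Matrix from [ancestry_dosage()] (individual x site).
#' @param cohort A cohort data.frame (rows matched by `individual_id`).
#' @param assessment_year Year used to convert birth year to age.
#' @return A `scan_result` data.frame: `site`, `effect`, `se`, `p`
#'   (NA at monomorphic-dosage sites).
#' @export
scan_linear <- function(dosage, cohort, assessment_year = 2008) {
  cohort <- as.data.frame(cohort)
  stopifnot(all(rownames(dosage) %in% cohort$individual_id))
  cohort <- cohort[match(rownames(dosage), cohort$individual_id), , drop = FALSE]
  y <- assessment_year - cohort$birth_year
  C <- .admixmap_design(cohort)
  # Frisch-Waugh: residualize age and dosage on the covariates once
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  rd <- qr.resid(qrC, dosage)
  ss_d <- colSums(rd^2)
  mono <- apply(dosage, 2, function(col) length(unique(col)) == 1) | ss_d < 1e-10
  beta <- colSums(rd * ry) / ss_d
  df <- nrow(C) - ncol(C) - 1
  rss <- sum(ry^2) - beta^2 * ss_d
  se <- sqrt(pmax(rss, 0) / df / ss_d)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(site = colnames(dosage) %||% seq_len(ncol(dosage)),
                    effect = ifelse(mono, NA_real_, beta),
                    se = ifelse(mono, NA_real_, se),
                    p = ifelse(mono, NA_real_, p),
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "model") <- "linear"
  out
}

#' Admixture-mapping logistic scan
#'
#' Splits the cohort into a younger (`birth_year >= split_year`) versus
#' older generation and fits, per site, a logistic regression of the
#' younger indicator on local-ancestry dosage with the same covariates as
#' [scan_linear()]. Sites with separation are flagged and get missing p.
#'
#' @param dosage Matrix from [ancestry_dosage()].
#' @param cohort A cohort data.frame.
#' @param split_year Dividing birth year (default 1965).
#' @return A `scan_result` data.frame: `site`, `effect`, `se`, `p`,
#'   `separation`.
#' @export
scan_logistic <- function(dosage, cohort, split_year = 1965) {
  cohort <- as.data.frame(cohort)
  stopifnot(all(rownames(dosage) %in% cohort$individual_id))
  cohort <- cohort[match(rownames(dosage), cohort$individual_id), , drop = FALSE]
  y <- as.integer(cohort$birth_year >= split_year)
  if (length(unique(y)) < 2) {
    config_error("split_year leaves one generation empty")
  }
  C <- .admixmap_design(cohort)
  m <- ncol(dosage)
  effect <- se <- p <- rep(NA_real_, m)
  sep <- logical(m)
  for (j in seq_len(m)) {
    d <- dosage[, j]
    if (length(unique(d)) == 1) next
    X <- cbind(dose = d, C)
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    if (!fit$converged) { sep[j] <- TRUE; next }
    cf <- fit$coefficients[1]
    # covariance from the weighted cross-product; flag separation by
    # exploding standard errors
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    cv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cv) || sqrt(cv[1, 1]) > 100) { sep[j] <- TRUE; next }
    effect[j] <- cf
    se[j] <- sqrt(cv[1, 1])
    p[j] <- 2 * stats::pnorm(-abs(cf / se[j]))
  }
  out <- data.frame(site = colnames(dosage) %||% seq_len(m),
                    effect = effect, se = se, p = p, separation = sep,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "model") <- "logistic"
  out
}

# spectral density at frequency zero of a series via an AR fit with
# AIC-selected order (the autoregression approach of MCMC effective-size
# estimators); returns the effective sample size of the series
.effective_size_ar <- function(x, max_order = 10) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-12) return(1) # constant series: one block
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(max_order, n - 1),
              method = "yule-walker", demean = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(n)
  if (fit$order == 0) return(n)
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  ess <- n * v / spec0
  min(n, max(1, ess))
}

#' Effective-number-of-tests significance threshold
#'
#' Local-ancestry dosages are strongly autocorrelated along a chromosome,
#' so the number of independent tests equals the number of ancestral
#' blocks, not the number of sites. Per individual and chromosome, the
#' dosage sequence's effective sample size is estimated as
#' `n * var / spec0`, with `spec0` the spectral density at zero from an
#' AIC-selected autoregressive fit; individual values are aggregated
#' (mean by default) per chromosome and summed over chromosomes, and the
#' genome-wide threshold is `alpha / total_blocks`.
#'
#' @param dosage Matrix from [ancestry_dosage()].
#' @param sites Site table with `chrom` and `pos` matching the dosage
#'   columns.
#' @param alpha Family-wise error target (default 0.05).
#' @param aggregate `"mean"` (default) or `"median"` across individuals.
#' @param max_order Maximum AR order considered.
#' @return A list: `threshold`, `total_blocks`, `per_chrom` (named
#'   vector), `alpha`.
#' @export
effective_tests_threshold <- function(dosage, sites, alpha = 0.05,
                                      aggregate = c("mean", "median"),
                                      max_order = 10) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  stopifnot(ncol(dosage) == nrow(sites))
  per_chrom <- c()
  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc)
    if (length(idx) < 2) config_error("need at least 2 sites per chromosome")
    idx <- idx[order(sites$pos[idx])]
    ess <- apply(dosage[, idx, drop = FALSE], 1,
                 .effective_size_ar, max_order = max_order)
    per_chrom[cc] <- agg_fun(ess)
  }
  total <- sum(per_chrom)
  list(threshold = alpha / total, total_blocks = total,
       per_chrom = per_chrom, alpha = alpha)
}
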