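#' Select polygenic-score SNPs by lowest p per window
#'
#' Restricts GWAS summary records to genome-wide significance
#' (`p < p_threshold`) and, within each non-overlapping window of
#' `window_bp` tiled from position 0 on each chromosome, keeps exactly the
#' record with the smallest p-value (ties broken by lowest position).
#'
#' @param records A `gwas_summary` data.frame (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `beta`, `p`).
#' @param p_threshold Significance threshold (default 5e-8).
#' @param window_bp Window size in bp (default 1 Mb).
#' @return The selected records, sorted by chromosome and position
#'   (possibly empty). Idempotent: re-applying returns the same set.
#' @export
select_prs_snps <- function(records, p_threshold = 5e-8, window_bp = 1e6) {
  stopifnot(all(c("chrom", "pos", "beta", "p") %in% names(records)))
  rec <- records[records$p < p_threshold, , drop = FALSE]
  if (nrow(rec) == 0) return(rec)
  win <- floor(rec$pos / window_bp)
  key <- paste(rec$chrom, win)
  rec <- rec[order(key, rec$p, rec$pos), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$chrom, floor(rec$pos / window_bp))), ,
             drop = FALSE]
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Compute polygenic height scores
#'
#' Per-individual weighted allele-dosage sum over the selected SNPs:
#' `score_i = sum_s beta_s * dosage_is`. Every selected SNP must be
#' present in the genotypes with a matching effect allele; missing
#' dosages are mean-imputed from the cohort allele frequency.
#'
#' @param geno A `hap_genotypes` object (the alternate allele is the
#'   effect allele, written as ALT in VCF output).
#' @param selected Selected records from [select_prs_snps()].
#' @param effect_allele The allele the genotypes count (default `"T"`,
#'   the generator's alternate allele).
#' @return Named numeric vector of scores, one per individual.
#' @export
compute_phs <- function(geno, selected, effect_allele = "T") {
  stopifnot(inherits(geno, "hap_genotypes"))
  if (nrow(selected) == 0) {
    return(stats::setNames(numeric(length(geno$individuals)), geno$individuals))
  }
  j <- match(selected$snp_id, geno$sites$snp_id)
  if (anyNA(j)) structural_error("selected SNPs missing from genotypes")
  if (!all(selected$effect_allele == effect_allele)) {
    structural_error("effect allele mismatch with no resolvable strand flip")
  }
  dos <- dosage_matrix(geno)[, j, drop = FALSE]
  if (anyNA(dos)) {
    fill <- matrix(rep(colMeans(dos, na.rm = TRUE), each = nrow(dos)),
                   nrow = nrow(dos))
    dos[is.na(dos)] <- fill[is.na(dos)]
  }
  as.numeric(dos %*% selected$beta) |> stats::setNames(rownames(dos))
}

#' Height-score association, pooled and by AI-ancestry quartile
#'
#' Regresses observed height on the polygenic height score while
#' controlling for log sampling weight, gender, recruitment center,
#' educational attainment, US-born status and number of US-born parents
#' (0 imputed for the non-US-born), in the pooled cohort and within each
#' quartile of global AI ancestry. Quartile edges are the cohort's
#' empirical 25/50/75 percentiles; intervals are left-closed and boundary
#' individuals fall in the lower quartile.
#'
#' @param cohort A cohort data.frame with `height`.
#' @param scores Named score vector from [compute_phs()].
#' @param quartile_variable Column defining the strata (default
#'   `"anc_ai"`).
#' @return A `phs_result` data.frame: `stratum` (`"all"`, `"Q1"`..`"Q4"`
#'   from lowest to highest ancestry), `n`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `p`.
#' @export
phs_height_association <- function(cohort, scores,
                                   quartile_variable = "anc_ai") {
  df <- as.data.frame(cohort)
  df$phs <- scores[df$individual_id]
  if (anyNA(df$phs)) structural_error("scores missing for some individuals")
  df$log_weight <- log(df$sampling_weight)
  df$n_us_born_parents0 <- ifelse(df$us_born, df$n_us_born_parents, 0L)
  covs <- intersect(c("log_weight", "gender", "center", "education",
                      "us_born", "n_us_born_parents0"), names(df))
  qv <- df[[quartile_variable]]
  edges <- stats::quantile(qv, c(0.25, 0.5, 0.75))
  # right-closed intervals put an individual sitting exactly on an edge in
  # the lower stratum
  stratum <- cut(qv, breaks = c(-Inf, edges, Inf),
                 labels = paste0("Q", 1:4), right = TRUE)
  fit_one <- function(dd, lab) {
    fml <- stats::reformulate(c("phs", covs), response = "height")
    ft <- .ols_trend_fit(fml, dd, "height", droppable = covs)
    cf <- ft$coefficients["phs", ]
    data.frame(stratum = lab, n = ft$n, estimate = cf$estimate, se = cf$se,
               ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, p = cf$p,
               stringsAsFactors = FALSE)
  }
  min_n <- 4 * (length(covs) + 2)
  if (nrow(df) < min_n) config_error("cohort too small for quartile stratification")
  out <- rbind(
    fit_one(df, "all"),
    do.call(rbind, lapply(levels(stratum), function(s) {
      fit_one(df[stratum == s, , drop = FALSE], s)
    }))
  )
  rownames(out) <- NULL
  attr(out, "quartile_edges") <- edges
  class(out) <- c("phs_result", "data.frame")
  out
}

#' Concordance of two allele-frequency vectors
#'
#' Pearson correlation with 95% confidence interval between matched
#' per-SNP allele frequencies (e.g. study sample versus external GWAS
#' panel).
#'
#' @param freqs_a,freqs_b Numeric vectors of equal length.
#' @return A data.frame: `n`, `r`, `ci_lo`, `ci_hi`, `p`.
#' @export
allele_freq_concordance <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b)) {
    structural_error("frequency vectors must be matched")
  }
  if (stats::sd(freqs_a) == 0 || stats::sd(freqs_b) == 0) {
    config_error("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(freqs_a, freqs_b, method = "pearson")
  data.frame(n = length(freqs_a), r = unname(ct$estimate),
             ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2], p = ct$p.value)
}
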