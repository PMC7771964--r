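# Diversity statistics computed inside local-ancestry tracts.
#
# The unit of comparison is a pair of haplotypes from two DIFFERENT
# individuals; a site enters a pair's comparison only where BOTH
# haplotypes carry the target ancestry at that site.

# internal: per-group site-wise counts for the streaming pi/F_ST engines.
# Returns list(A = hap x site label indicator, X = hap x site alleles,
# ind = individual of each hap row)
.hap_site_setup <- function(tracts, geno, label) {
  A <- tract_labels_at_sites(tracts, geno$sites) == label
  A[is.na(A)] <- FALSE
  X <- geno$alleles[rownames(A), , drop = FALSE]
  ind <- sub("\\|[01]$", "", rownames(A))
  list(A = A, X = X, ind = ind)
}

# streaming pi for one set of individuals; returns c(diffs, pairs)
.pi_counts <- function(setup, individuals) {
  sel <- setup$ind %in% individuals
  A <- setup$A[sel, , drop = FALSE]
  X <- setup$X[sel, , drop = FALSE] * A # zero out non-target sites
  ind <- setup$ind[sel]
  n_lab <- colSums(A)
  n_one <- colSums(X)
  tot_pairs <- n_lab * (n_lab - 1) / 2
  tot_diffs <- n_one * (n_lab - n_one)
  # exclude within-individual pairs ("across individuals")
  o <- order(ind)
  A <- A[o, , drop = FALSE]; X <- X[o, , drop = FALSE]
  odd <- seq(1, nrow(A), by = 2)
  both <- A[odd, , drop = FALSE] & A[odd + 1, , drop = FALSE]
  disc <- both & (X[odd, , drop = FALSE] != X[odd + 1, , drop = FALSE])
  c(diffs = sum(tot_diffs) - sum(disc), pairs = sum(tot_pairs) - sum(both))
}

#' Nucleotide diversity within ancestry tracts, by group
#'
#' For every pair of haplotypes from distinct individuals within a group,
#' allelic differences are counted at sites where both haplotypes carry
#' the target ancestry; pi is total differences divided by total
#' comparable (haplotype-pair x site) comparisons. Confidence intervals
#' come from a block bootstrap over individuals.
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param geno A `hap_genotypes` object.
#' @param groups Named vector/factor: group of each individual (names are
#'   individual ids), e.g. birth decade crossed with US-born status.
#' @param label Target ancestry (default `"AI"`).
#' @param n_boot Bootstrap iterations for the 95% CI (0 disables).
#' @param seed Seed for the bootstrap.
#' @return A `diversity_table` data.frame: `group`, `n_individuals`,
#'   `n_comparisons`, `pi`, `ci_lo`, `ci_hi`.
#' @export
pi_within_ancestry <- function(tracts, geno, groups, label = "AI",
                               n_boot = 200, seed = 1) {
  stopifnot(inherits(geno, "hap_genotypes"))
  if (is.null(names(groups))) structural_error("groups must be named by individual id")
  setup <- .hap_site_setup(tracts, geno, label)
  set.seed(seed)
  levs <- sort(unique(as.character(groups)))
  rows <- vector("list", length(levs))
  for (i in seq_along(levs)) {
    ids <- names(groups)[as.character(groups) == levs[i]]
    ids <- intersect(ids, geno$individuals)
    if (length(ids) < 2) {
      warning("group '", levs[i], "' has fewer than 2 individuals; skipped")
      rows[[i]] <- data.frame(group = levs[i], n_individuals = length(ids),
                              n_comparisons = 0, pi = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_)
      next
    }
    ct <- .pi_counts(setup, ids)
    pi_hat <- if (ct["pairs"] > 0) ct["diffs"] / ct["pairs"] else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && !is.na(pi_hat)) {
      bs <- replicate(n_boot, {
        bids <- sample(ids, length(ids), replace = TRUE)
        # resampling with replacement can duplicate ids; pairs within a
        # duplicated individual are still excluded by id, a conservative rule
        cb <- .pi_counts(setup, unique(bids))
        if (cb["pairs"] > 0) cb["diffs"] / cb["pairs"] else NA_real_
      })
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
    }
    rows[[i]] <- data.frame(group = levs[i], n_individuals = length(ids),
                            n_comparisons = unname(ct["pairs"]),
                            pi = unname(pi_hat),
                            ci_lo = unname(ci[1]), ci_hi = unname(ci[2]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

# per-site frequency and haplotype count of the target ancestry for a set
# of individuals
.lab_freqs <- function(setup, individuals) {
  sel <- setup$ind %in% individuals
  A <- setup$A[sel, , drop = FALSE]
  X <- setup$X[sel, , drop = FALSE]
  n <- colSums(A)
  p <- ifelse(n > 0, colSums(X * A) / n, NA_real_)
  list(p = p, n = n)
}

#' F_ST between groups within ancestry tracts
#'
#' Per site, `H_T` is the heterozygosity `2p(1-p)` of the pooled target-
#' ancestry haplotypes of the two groups and `H_S` the unweighted mean of
#' the within-group heterozygosities; F_ST is
#' `(mean H_T - mean H_S) / mean H_T` over sites with at least
#' `min_haps` target haplotypes in each group. Negative values arise when
#' within-group heterozygosity exceeds the pooled value and are reported
#' as such.
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param geno A `hap_genotypes` object.
#' @param groups Named vector/factor: group per individual.
#' @param label Target ancestry.
#' @param pairs Optional 2-column matrix/data.frame of group pairs;
#'   default all unordered pairs of levels.
#' @param min_haps Minimum target haplotypes per group per site
#'   (default 2).
#' @param unbiased Apply the small-sample correction `n/(n-1)` to each
#'   heterozygosity (default `FALSE`: plain `2p(1-p)` from sample
#'   frequencies, which carries a positive bias of roughly half the
#'   reciprocal group size for exchangeable groups).
#' @return A `diversity_table` data.frame: `group_1`, `group_2`,
#'   `n_sites`, `fst` (NA when the comparison set is monomorphic).
#' @export
fst_between_groups <- function(tracts, geno, groups, label = "AI",
                               pairs = NULL, min_haps = 2,
                               unbiased = FALSE) {
  stopifnot(inherits(geno, "hap_genotypes"))
  setup <- .hap_site_setup(tracts, geno, label)
  levs <- sort(unique(as.character(groups)))
  if (is.null(pairs)) {
    if (length(levs) < 2) config_error("need at least two groups")
    pairs <- t(utils::combn(levs, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g1 <- names(groups)[as.character(groups) == pairs[k, 1]]
    g2 <- names(groups)[as.character(groups) == pairs[k, 2]]
    f1 <- .lab_freqs(setup, g1)
    f2 <- .lab_freqs(setup, g2)
    ok <- f1$n >= min_haps & f2$n >= min_haps
    if (!any(ok)) {
      rows[[k]] <- data.frame(group_1 = pairs[k, 1], group_2 = pairs[k, 2],
                              n_sites = 0L, fst = NA_real_)
      next
    }
    n1 <- f1$n[ok]; n2 <- f2$n[ok]
    p_t <- (f1$p[ok] * n1 + f2$p[ok] * n2) / (n1 + n2)
    h_t <- 2 * p_t * (1 - p_t)
    h1 <- 2 * f1$p[ok] * (1 - f1$p[ok])
    h2 <- 2 * f2$p[ok] * (1 - f2$p[ok])
    if (unbiased) {
      h_t <- h_t * (n1 + n2) / (n1 + n2 - 1)
      h1 <- h1 * n1 / (n1 - 1)
      h2 <- h2 * n2 / (n2 - 1)
    }
    h_s <- (h1 + h2) / 2
    mh_t <- mean(h_t)
    fst <- if (mh_t > 0) (mh_t - mean(h_s)) / mh_t else NA_real_
    rows[[k]] <- data.frame(group_1 = pairs[k, 1], group_2 = pairs[k, 2],
                            n_sites = sum(ok), fst = fst)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Tract-length distribution regression across birth decades
#'
#' Bins AI tract lengths into logarithmically spaced bins, forms the
#' matrix `f[T, A]` of the proportion of total AI tract length falling in
#' length bin `T` for birth decade `A` (each decade's proportions sum to
#' 1; empty cells get half the smallest positive proportion as a
#' pseudo-count), and fits `log(f) = b0 + b1 T + b2 A + b3 T A` with
#' ordinal codes for bin and decade. `b3` tests whether the tract-length
#' distribution shifts across decades; `b2` is the decade main effect.
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param decades Named vector: birth decade per individual id.
#' @param label Target ancestry.
#' @param n_bins Number of length bins (default 10).
#' @param min_length Lower edge of the first bin in bp (default 1e6, a
#'   1 cM equivalent at 1 cM/Mb).
#' @return A `trend_fit`-like list with the coefficient table, plus
#'   `f_matrix` and `bin_edges`.
#' @export
tract_length_regression <- function(tracts, decades, label = "AI",
                                    n_bins = 10, min_length = 1e6) {
  tt <- tracts[tracts$label == label, , drop = FALSE]
  if (nrow(tt) == 0) structural_error("no tracts with the requested label")
  if (is.null(names(decades))) structural_error("decades must be named by individual id")
  len <- tt$end - tt$start
  max_len <- max(len)
  if (max_len <= min_length) config_error("all tracts shorter than min_length")
  edges <- exp(seq(log(min_length), log(max_len + 1), length.out = n_bins + 1))
  edges[1] <- 0 # first bin absorbs sub-threshold tracts
  dec <- decades[tt$individual_id]
  dec_levels <- sort(unique(stats::na.omit(as.numeric(decades))))
  bin <- cut(len, breaks = edges, labels = FALSE, include.lowest = TRUE, right = FALSE)
  f <- matrix(0, nrow = n_bins, ncol = length(dec_levels),
              dimnames = list(NULL, dec_levels))
  agg <- stats::aggregate(len, by = list(bin = bin, dec = as.numeric(dec)), FUN = sum)
  for (r in seq_len(nrow(agg))) {
    f[agg$bin[r], as.character(agg$dec[r])] <- agg$x[r]
  }
  f <- sweep(f, 2, colSums(f), "/")
  if (any(colSums(f) == 0)) structural_error("a decade has no tract length at all")
  pos_min <- min(f[f > 0])
  f[f == 0] <- pos_min / 2
  f <- sweep(f, 2, colSums(f), "/") # renormalize after pseudo-counts
  df <- data.frame(
    logf = as.vector(log(f)),
    T_bin = rep(seq_len(n_bins) - 1L, times = length(dec_levels)),
    A_dec = rep(seq_along(dec_levels) - 1L, each = n_bins)
  )
  fit <- stats::lm(logf ~ T_bin * A_dec, data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  tab <- data.frame(estimate = sm$coefficients[, 1], se = sm$coefficients[, 2],
                    ci_lo = ci[, 1], ci_hi = ci[, 2], p = sm$coefficients[, 4])
  out <- list(coefficients = tab, r_squared = sm$r.squared,
              n = nrow(df), response = "log tract-length proportion",
              fit = fit, f_matrix = f, bin_edges = edges)
  class(out) <- "trend_fit"
  out
}

#' Per-individual AI fraction from tract lengths
#'
#' Sums tract lengths per individual and returns the fraction of the
#' diploid genome covered by tracts of the target label; when the cohort
#' is supplied, the global ancestry estimate is attached for concordance
#' checks.
#'
#' @param tracts An `ancestry_tracts` data.frame tiling the genome.
#' @param cohort Optional cohort with `anc_ai` for comparison.
#' @param label Target ancestry.
#' @param map Genome map for tiling validation (defaults to the one
#'   attached to `tracts`).
#' @return A data.frame: `individual_id`, `tract_fraction`, and if the
#'   cohort is given `anc_ai` and `difference`.
#' @export
tract_global_concordance <- function(tracts, cohort = NULL, label = "AI",
                                     map = attr(tracts, "map")) {
  if (is.null(tracts) || nrow(tracts) == 0) structural_error("empty tract set")
  validate_tract_tiling(tracts, map)
  len <- tracts$end - tracts$start
  tot <- tapply(len, tracts$individual_id, sum)
  lab <- tapply(len * (tracts$label == label), tracts$individual_id, sum)
  out <- data.frame(individual_id = names(tot),
                    tract_fraction = as.numeric(lab / tot),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    out$anc_ai <- cohort$anc_ai[match(out$individual_id, cohort$individual_id)]
    out$difference <- out$tract_fraction - out$anc_ai
  }
  rownames(out) <- NULL
  out
}
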