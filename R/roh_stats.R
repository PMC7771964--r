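#' Fixed ROH size-class boundaries
#'
#' The short/medium (A/B) and medium/long (B/C) boundaries reported for
#' the Mexican American call set: 845,097 bp and 2,501,750 bp.
#'
#' @return A `class_boundaries` list with `ab_boundary`, `bc_boundary`,
#'   `source = "fixed"`.
#' @export
fixed_class_boundaries <- function() {
  out <- list(ab_boundary = 845097, bc_boundary = 2501750, source = "fixed")
  class(out) <- "class_boundaries"
  out
}

#' Fit ROH size-class boundaries with a Gaussian mixture
#'
#' Fits a three-component Gaussian mixture to segment lengths by EM
#' (unequal variances) and places the A/B and B/C boundaries where the
#' posterior responsibility switches between adjacent components, found by
#' root-finding between the sorted component means.
#'
#' @param lengths Positive segment lengths in bp (>= 30 values).
#' @param n_components Number of mixture components (3).
#' @param log_scale Fit on log-lengths instead of raw bp.
#' @param seed Seed for the jittered refit fallback.
#' @return A `class_boundaries` list with `ab_boundary`, `bc_boundary`,
#'   `source = "fitted"` and the mixture `model`.
#' @export
fit_class_boundaries <- function(lengths, n_components = 3, log_scale = FALSE,
                                 seed = 1) {
  if (length(lengths) < 30) config_error("need at least 30 lengths")
  if (any(lengths <= 0)) config_error("lengths must be positive")
  x <- if (log_scale) log(lengths) else as.numeric(lengths)
  fit <- tryCatch(
    mclust::Mclust(x, G = n_components, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    # component collapse: jitter and refit once
    set.seed(seed)
    x2 <- x + stats::rnorm(length(x), 0, stats::sd(x) * 1e-3)
    fit <- mclust::Mclust(x2, G = n_components, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) stop("Gaussian mixture fit failed after jittered refit")
  }
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, n_components)
  pr <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; pr <- pr[o]
  crossover <- function(i, j) {
    g <- function(v) {
      log(pr[i]) + stats::dnorm(v, mu[i], sg[i], log = TRUE) -
        log(pr[j]) - stats::dnorm(v, mu[j], sg[j], log = TRUE)
    }
    lo <- mu[i]; hi <- mu[j]
    if (g(lo) * g(hi) > 0) return((mu[i] + mu[j]) / 2) # no sign change: midpoint
    stats::uniroot(g, c(lo, hi))$root
  }
  ab <- crossover(1, 2)
  bc <- crossover(2, 3)
  if (log_scale) { ab <- exp(ab); bc <- exp(bc) }
  out <- list(ab_boundary = ab, bc_boundary = bc, source = "fitted",
              model = list(mean = mu, sd = sg, pro = pr))
  class(out) <- "class_boundaries"
  out
}

#' Assign ROH size classes
#'
#' `length < ab` is class A (short), `ab <= length < bc` class B
#' (medium), `length >= bc` class C (long).
#'
#' @param segments A `roh_segments` data.frame with `length` (or
#'   `start`/`end`).
#' @param boundaries A `class_boundaries` object.
#' @return The segments with a `size_class` factor column.
#' @export
#' @examples
#' seg <- data.frame(individual_id = "a", chrom = "chr1",
#'                   start = 0, end = 1e6, length = 1e6)
#' classify_roh(seg, fixed_class_boundaries())$size_class
classify_roh <- function(segments, boundaries) {
  stopifnot(inherits(boundaries, "class_boundaries") ||
              all(c("ab_boundary", "bc_boundary") %in% names(boundaries)))
  if (boundaries$ab_boundary <= 0 ||
      boundaries$ab_boundary >= boundaries$bc_boundary) {
    config_error("boundaries must satisfy 0 < ab < bc")
  }
  len <- segments$length %||% (segments$end - segments$start)
  segments$size_class <- factor(
    ifelse(len < boundaries$ab_boundary, "A",
           ifelse(len < boundaries$bc_boundary, "B", "C")),
    levels = c("A", "B", "C"))
  segments
}

# per-chromosome IRanges of positions where BOTH haplotypes of one
# individual carry `label` ("both" rule), or of each haplotype ("mean")
.label_ranges <- function(tr_ind, label, chroms) {
  out <- list()
  for (cc in chroms) {
    tc <- tr_ind[tr_ind$chrom == cc & tr_ind$label == label, , drop = FALSE]
    h0 <- tc[tc$haplotype == 0, , drop = FALSE]
    h1 <- tc[tc$haplotype == 1, , drop = FALSE]
    r0 <- IRanges::IRanges(start = h0$start + 1, end = h0$end)
    r1 <- IRanges::IRanges(start = h1$start + 1, end = h1$end)
    out[[cc]] <- list(h0 = r0, h1 = r1,
                      both = IRanges::intersect(r0, r1))
  }
  out
}

#' ROH overlap with local-ancestry tracts
#'
#' Intersects each individual's ROH with their ancestry tracts and sums
#' the overlapping bp per ancestry label and size class. ROH are unphased
#' diploid intervals while tracts are per-haplotype, so a diploid rule is
#' needed: under the default `"both"` rule a base counts as overlapping
#' ancestry k only when BOTH haplotypes carry k there (ROH implies locally
#' identical haplotypes); the `"mean"` rule averages the two haplotypes'
#' indicator instead.
#'
#' @param segments Classified ROH (see [classify_roh()]).
#' @param tracts An `ancestry_tracts` data.frame.
#' @param rule `"both"` (default) or `"mean"`.
#' @param cohort Optional cohort; when given, overlaps are also
#'   normalized by the individual's global ancestry of each label.
#' @return A data.frame: `individual_id`, `label`, `size_class`, `bp`,
#'   and `bp_normalized` when a cohort is supplied. Individuals without
#'   tracts get zero rows.
#' @export
overlap_by_ancestry <- function(segments, tracts, rule = c("both", "mean"),
                                cohort = NULL) {
  rule <- match.arg(rule)
  if (!"size_class" %in% names(segments)) {
    segments <- classify_roh(segments, fixed_class_boundaries())
  }
  labels <- c("AFR", "EUR", "AI")
  classes <- c("A", "B", "C")
  individuals <- unique(c(segments$individual_id, tracts$individual_id))
  chroms <- unique(tracts$chrom)
  grid <- expand.grid(individual_id = individuals, label = labels,
                      size_class = classes, stringsAsFactors = FALSE)
  grid$bp <- 0
  key <- paste(grid$individual_id, grid$label, grid$size_class)
  bp <- stats::setNames(grid$bp, key)

  seg_by_ind <- split(segments, segments$individual_id)
  tr_by_ind <- split(as.data.frame(tracts)[c("haplotype", "chrom", "start",
                                             "end", "label")],
                     tracts$individual_id)
  for (id in names(seg_by_ind)) {
    tr_ind <- tr_by_ind[[id]]
    if (is.null(tr_ind)) next # no tracts: zeros
    seg <- seg_by_ind[[id]]
    for (lb in labels) {
      lr <- .label_ranges(tr_ind, lb, chroms)
      for (cl in classes) {
        sc <- seg[seg$size_class == cl, , drop = FALSE]
        if (nrow(sc) == 0) next
        tot <- 0
        for (cc in unique(sc$chrom)) {
          rr <- IRanges::IRanges(start = sc$start[sc$chrom == cc] + 1,
                                 end = sc$end[sc$chrom == cc])
          rr <- IRanges::reduce(rr)
          if (is.null(lr[[cc]])) next
          if (rule == "both") {
            tot <- tot + sum(IRanges::width(IRanges::intersect(rr, lr[[cc]]$both)))
          } else {
            tot <- tot +
              (sum(IRanges::width(IRanges::intersect(rr, lr[[cc]]$h0))) +
                 sum(IRanges::width(IRanges::intersect(rr, lr[[cc]]$h1)))) / 2
          }
        }
        bp[paste(id, lb, cl)] <- tot
      }
    }
  }
  grid$bp <- unname(bp[key])
  if (!is.null(cohort)) {
    anc_col <- c(AFR = "anc_afr", EUR = "anc_eur", AI = "anc_ai")
    anc <- mapply(function(id, lb) {
      cohort[[anc_col[[lb]]]][match(id, cohort$individual_id)]
    }, grid$individual_id, grid$label)
    grid$bp_normalized <- ifelse(anc > 0, grid$bp / anc, NA_real_)
  }
  grid
}

#' Birth-year trends of ROH burden (Kendall's tau)
#'
#' Kendall's tau-b with asymptotic p between birth year and per-individual
#' ROH overlap quantities: the total across size classes per ancestry and
#' each size class separately, on raw and (when available) ancestry-
#' normalized scales.
#'
#' @param overlaps Output of [overlap_by_ancestry()].
#' @param cohort A cohort data.frame with `birth_year`.
#' @param labels Ancestry labels to test.
#' @return A data.frame: `label`, `size_class` (`"total"` for the sum),
#'   `normalized`, `n`, `tau`, `p` (NA when the quantity is constant).
#' @export
roh_trend <- function(overlaps, cohort, labels = c("AI", "EUR")) {
  if (nrow(cohort) < 10) config_error("need at least 10 individuals")
  by <- stats::setNames(cohort$birth_year, cohort$individual_id)
  has_norm <- "bp_normalized" %in% names(overlaps)
  one <- function(values, ids, lb, cl, norm) {
    yy <- by[ids]
    ok <- !is.na(values) & !is.na(yy)
    if (sum(ok) < 10 || stats::sd(values[ok]) == 0 || stats::sd(yy[ok]) == 0) {
      return(data.frame(label = lb, size_class = cl, normalized = norm,
                        n = sum(ok), tau = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(yy[ok], values[ok],
                                           method = "kendall"))
    data.frame(label = lb, size_class = cl, normalized = norm, n = sum(ok),
               tau = unname(ct$estimate), p = ct$p.value)
  }
  rows <- list()
  for (lb in labels) {
    ov <- overlaps[overlaps$label == lb, , drop = FALSE]
    tot <- tapply(ov$bp, ov$individual_id, sum)
    rows[[length(rows) + 1]] <- one(as.numeric(tot), names(tot), lb, "total", FALSE)
    for (cl in unique(as.character(ov$size_class))) {
      oc <- ov[ov$size_class == cl, , drop = FALSE]
      rows[[length(rows) + 1]] <- one(oc$bp, oc$individual_id, lb, cl, FALSE)
      if (has_norm) {
        rows[[length(rows) + 1]] <- one(oc$bp_normalized, oc$individual_id,
                                        lb, cl, TRUE)
      }
    }
    if (has_norm) {
      totn <- tapply(ov$bp_normalized, ov$individual_id, sum)
      rows[[length(rows) + 1]] <- one(as.numeric(totn), names(totn), lb,
                                      "total", TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
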