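#' Generate phased local-ancestry tracts
#'
#' Emulates the output of a local-ancestry caller for an admixed cohort.
#' For each individual, haplotype and chromosome, ancestry switch points
#' are laid down as a Poisson process at `lambda_gens` per Morgan (the
#' admixture age in generations), and each segment's ancestry label is an
#' independent draw from the individual's global proportions; adjacent
#' equal labels are merged. The resulting Markov switching process has the
#' individual's global proportions as its stationary distribution, so the
#' mean tract length of ancestry k is `1 / (lambda_gens * (1 - p_k))`
#' Morgans and the genome-wide AI tract fraction reproduces `anc_ai` in
#' expectation.
#'
#' @param cohort A cohort data.frame with `anc_afr`, `anc_eur`, `anc_ai`.
#' @param map A [genome_map()].
#' @param lambda_gens Admixture age in generations (switch rate per
#'   Morgan); default 10.
#' @param seed Integer seed.
#' @return An `ancestry_tracts` data.frame with columns `individual_id`,
#'   `haplotype` (0/1), `chrom`, `start`, `end` (bp, 0-based half-open)
#'   and `label` in `{AFR, EUR, AI}`. Tracts tile every chromosome.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5), seed = 1)
#' tr <- generate_local_ancestry(coh, default_genome_map(), seed = 1)
generate_local_ancestry <- function(cohort, map, lambda_gens = 10, seed = 1) {
  if (!is_genome_map(map)) structural_error("map is not a genome_map")
  if (!all(c("anc_afr", "anc_eur", "anc_ai") %in% names(cohort))) {
    structural_error("cohort lacks global ancestry proportions")
  }
  if (lambda_gens <= 0) config_error("lambda_gens must be positive")
  set.seed(seed)
  labels <- c("AFR", "EUR", "AI")
  out <- vector("list", nrow(cohort) * 2L * nrow(map))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    probs <- c(cohort$anc_afr[i], cohort$anc_eur[i], cohort$anc_ai[i])
    for (hap in 0:1) {
      for (cc in seq_len(nrow(map))) {
        L_m <- map$length_morgans[cc]
        L_bp <- map$length_bp[cc]
        nb <- stats::rpois(1, lambda_gens * L_m)
        # breakpoints in bp under a uniform genetic map
        brk <- sort(as.numeric(unique(round(stats::runif(nb, 0, L_bp)))))
        brk <- brk[brk > 0 & brk < L_bp]
        bounds <- c(0, brk, L_bp)
        nseg <- length(bounds) - 1L
        lab <- sample(labels, nseg, replace = TRUE, prob = probs)
        # merge adjacent equal labels
        keep <- c(TRUE, lab[-1] != lab[-nseg])
        starts <- bounds[-length(bounds)][keep]
        ends <- c(starts[-1], L_bp)
        k <- k + 1L
        out[[k]] <- data.frame(
          individual_id = cohort$individual_id[i],
          haplotype = hap,
          chrom = map$chrom[cc],
          start = starts,
          end = ends,
          label = lab[keep],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tracts <- do.call(rbind, out[seq_len(k)])
  rownames(tracts) <- NULL
  attr(tracts, "map") <- map
  attr(tracts, "lambda_gens") <- lambda_gens
  class(tracts) <- c("ancestry_tracts", "data.frame")
  tracts
}

#' Check that tracts tile the genome
#'
#' For every individual, haplotype and chromosome, the sorted tracts must
#' satisfy `end_i = start_(i+1)`, start at 0 and end at the chromosome
#' length.
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param map A [genome_map()]; defaults to the map attached to `tracts`.
#' @return Invisibly `TRUE`; otherwise a structural error.
#' @export
validate_tract_tiling <- function(tracts, map = attr(tracts, "map")) {
  if (is.null(tracts) || nrow(tracts) == 0) structural_error("empty tract set")
  if (is.null(map)) structural_error("no genome map available")
  lens <- map_chrom_lengths(map)
  key <- paste(tracts$individual_id, tracts$haplotype, tracts$chrom)
  ord <- order(key, tracts$start)
  t2 <- tracts[ord, ]
  k2 <- key[ord]
  first <- !duplicated(k2)
  last <- !duplicated(k2, fromLast = TRUE)
  if (any(t2$start[first] != 0)) structural_error("a haplotype does not start at 0")
  if (any(abs(t2$end[last] - lens[t2$chrom[last]]) > 0)) {
    structural_error("a haplotype does not end at the chromosome length")
  }
  inner <- !last
  nxt <- which(inner) + 1L
  if (any(t2$end[inner] != t2$start[nxt])) {
    structural_error("tracts have gaps or overlaps")
  }
  invisible(TRUE)
}
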