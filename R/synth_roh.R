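#' Configuration for the synthetic ROH generator
#'
#' Segment lengths follow a three-component log-normal mixture whose
#' components mimic the short (tens of kb), medium (hundreds of kb) and
#' long (megabase-scale) runs-of-homozygosity classes; the expected number
#' of segments per individual follows a linear birth-year trend.
#'
#' @param mean_segments Expected segments per individual at the midpoint
#'   birth year.
#' @param segments_by_slope Change in expected segments per birth year
#'   (positive = younger individuals carry more ROH).
#' @param mix_weights Mixture weights of the short/medium/long components.
#' @param mix_meanlog,mix_sdlog Log-scale means and sds of the component
#'   length distributions (bp); component means must be increasing.
#' @return A `roh_config` list.
#' @export
roh_config <- function(mean_segments = 30, segments_by_slope = 0.1,
                       mix_weights = c(0.65, 0.27, 0.08),
                       mix_meanlog = log(c(6e4, 4e5, 3e6)),
                       mix_sdlog = c(0.45, 0.4, 0.35)) {
  if (mean_segments < 0) config_error("mean_segments must be nonnegative")
  if (length(mix_weights) != 3 || any(mix_weights < 0) ||
      abs(sum(mix_weights) - 1) > 1e-6) {
    config_error("mix_weights must be three nonnegative values summing to 1")
  }
  if (is.unsorted(mix_meanlog, strictly = TRUE)) {
    config_error("mixture component means must be increasing (short < medium < long)")
  }
  cfg <- list(mean_segments = mean_segments,
              segments_by_slope = segments_by_slope,
              mix_weights = mix_weights,
              mix_meanlog = mix_meanlog, mix_sdlog = mix_sdlog)
  class(cfg) <- "roh_config"
  cfg
}

#' Generate synthetic ROH segments
#'
#' Per individual, the segment count is Poisson with a linear-in-birth-year
#' mean; each segment's length is drawn from the configured log-normal
#' mixture, placed uniformly on a chromosome chosen proportionally to
#' physical length, and clipped to fit.
#'
#' @param cohort A cohort data.frame.
#' @param map A [genome_map()].
#' @param config A [roh_config()].
#' @param seed Integer seed.
#' @return A `roh_segments` data.frame with `individual_id`, `chrom`,
#'   `start`, `end`, `length` (bp, 0-based half-open).
#' @export
generate_roh <- function(cohort, map, config = roh_config(), seed = 1) {
  stopifnot(inherits(config, "roh_config"))
  if (!is_genome_map(map)) structural_error("map is not a genome_map")
  set.seed(seed)
  by_mid <- mean(range(cohort$birth_year))
  lam <- pmax(0, config$mean_segments +
                config$segments_by_slope * (cohort$birth_year - by_mid))
  n_seg <- stats::rpois(nrow(cohort), lam)
  total <- sum(n_seg)
  if (total == 0) {
    out <- data.frame(individual_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), length = numeric(0))
    class(out) <- c("roh_segments", "data.frame")
    return(out)
  }
  comp <- sample.int(3, total, replace = TRUE, prob = config$mix_weights)
  len <- round(stats::rlnorm(total, config$mix_meanlog[comp],
                             config$mix_sdlog[comp]))
  cc <- sample.int(nrow(map), total, replace = TRUE,
                   prob = map$length_bp / sum(map$length_bp))
  L <- map$length_bp[cc]
  len <- pmin(len, L)
  start <- floor(stats::runif(total, 0, L - len + 1))
  out <- data.frame(
    individual_id = rep(cohort$individual_id, n_seg),
    chrom = map$chrom[cc],
    start = start,
    end = start + len,
    length = len,
    stringsAsFactors = FALSE
  )
  attr(out, "map") <- map
  class(out) <- c("roh_segments", "data.frame")
  out
}
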