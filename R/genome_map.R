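#' Construct a genome map
#'
#' A genome map lists the chromosomes over which tracts, genotypes and ROH
#' live: name, physical length in bp and genetic length in Morgans.
#' Coordinates are 0-based half-open throughout the package and converted
#' to 1-based only when writing VCF.
#'
#' @param length_bp Positive numeric vector of chromosome lengths in bp.
#' @param cm_per_mb Recombination rate used to derive genetic lengths
#'   (default 1 cM/Mb, a genome-wide average).
#' @param names Chromosome names; default `"chr1"`, `"chr2"`, ...
#' @return A `genome_map` data.frame with columns `chrom`, `length_bp`,
#'   `length_morgans`.
#' @export
#' @examples
#' genome_map(c(5e7, 5e7))
genome_map <- function(length_bp, cm_per_mb = 1, names = NULL) {
  if (length(length_bp) < 1 || any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    config_error("chromosome lengths must be positive and finite")
  }
  if (cm_per_mb <= 0) config_error("cm_per_mb must be positive")
  names <- names %||% paste0("chr", seq_along(length_bp))
  if (anyDuplicated(names)) config_error("chromosome names must be unique")
  map <- data.frame(
    chrom = as.character(names),
    length_bp = as.numeric(length_bp),
    length_morgans = as.numeric(length_bp) / 1e6 * cm_per_mb / 100,
    stringsAsFactors = FALSE
  )
  class(map) <- c("genome_map", "data.frame")
  map
}

#' Default desk-scale genome map
#'
#' Four chromosomes of 50 Mb at 1 cM/Mb: large enough for tract and
#' diversity statistics to be well behaved, small enough for seconds-scale
#' tests.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Length of each chromosome in bp.
#' @param cm_per_mb Recombination rate.
#' @return A [genome_map()].
#' @export
default_genome_map <- function(n_chrom = 4, chrom_bp = 5e7, cm_per_mb = 1) {
  genome_map(rep(chrom_bp, n_chrom), cm_per_mb = cm_per_mb)
}

is_genome_map <- function(x) {
  inherits(x, "genome_map") ||
    (is.data.frame(x) && all(c("chrom", "length_bp", "length_morgans") %in% names(x)))
}

map_chrom_lengths <- function(map) {
  stats::setNames(map$length_bp, map$chrom)
}
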