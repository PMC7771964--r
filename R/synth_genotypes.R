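#' Ancestry panel allele frequencies under Balding-Nichols divergence
#'
#' Draws per-site allele frequencies for the three ancestral panels (AFR,
#' EUR, AI) around a shared ancestral frequency using the Balding-Nichols
#' model: panel frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) with divergence
#' parameter `F = fst_target`. `fst_target = 0` makes the three panels
#' identical to the ancestral frequency.
#'
#' @param map A [genome_map()].
#' @param n_sites Total number of biallelic sites, allocated to
#'   chromosomes proportionally to physical length (default 2000).
#' @param fst_target Balding-Nichols divergence parameter in \[0,1).
#' @param base_freq_range Range of the ancestral allele frequency.
#' @param seed Integer seed.
#' @return A `panel_freqs` data.frame with columns `snp_id`, `chrom`,
#'   `pos` (0-based, strictly increasing per chromosome), `p_afr`,
#'   `p_eur`, `p_ai` and the ancestral `p_anc`.
#' @export
ancestry_panel_freqs <- function(map, n_sites = 2000, fst_target = 0.1,
                                 base_freq_range = c(0.05, 0.95), seed = 1) {
  if (!is_genome_map(map)) structural_error("map is not a genome_map")
  if (fst_target < 0 || fst_target >= 1) config_error("fst_target must be in [0,1)")
  if (n_sites < 1) config_error("n_sites must be positive")
  set.seed(seed)
  alloc <- pmax(1L, round(n_sites * map$length_bp / sum(map$length_bp)))
  rows <- vector("list", nrow(map))
  for (cc in seq_len(nrow(map))) {
    m <- alloc[cc]
    # evenly spread sites with a jitter, keeping positions strictly increasing
    spacing <- map$length_bp[cc] / (m + 1)
    pos <- round(spacing * seq_len(m) +
                   stats::runif(m, -0.3 * spacing, 0.3 * spacing))
    pos <- pmin(pmax(pos, 0), map$length_bp[cc] - 1)
    pos <- sort(unique(pos))
    m <- length(pos)
    p_anc <- stats::runif(m, base_freq_range[1], base_freq_range[2])
    if (fst_target == 0) {
      p_afr <- p_eur <- p_ai <- p_anc
    } else {
      shape <- (1 - fst_target) / fst_target
      bn <- function() stats::rbeta(m, p_anc * shape, (1 - p_anc) * shape)
      p_afr <- bn(); p_eur <- bn(); p_ai <- bn()
    }
    rows[[cc]] <- data.frame(
      snp_id = sprintf("%s_snp%05d", map$chrom[cc], seq_len(m)),
      chrom = map$chrom[cc], pos = pos,
      p_afr = p_afr, p_eur = p_eur, p_ai = p_ai, p_anc = p_anc,
      stringsAsFactors = FALSE
    )
  }
  freqs <- do.call(rbind, rows)
  rownames(freqs) <- NULL
  attr(freqs, "fst_target") <- fst_target
  attr(freqs, "map") <- map
  class(freqs) <- c("panel_freqs", "data.frame")
  freqs
}

#' Generate phased genotypes on local-ancestry tracts
#'
#' Each haplotype's allele at a site is a Bernoulli draw from the panel
#' frequency of the ancestry of the tract covering that site, so the
#' genotypes carry exactly the ancestry structure encoded in the tracts.
#'
#' @param tracts An `ancestry_tracts` data.frame tiling the genome.
#' @param freqs An [ancestry_panel_freqs()] table.
#' @param seed Integer seed.
#' @return A `hap_genotypes` list: `sites` (the `freqs` site table),
#'   `alleles` (integer 0/1 matrix, one row per haplotype named
#'   `"<individual>|<hap>"`), `individuals`.
#' @export
generate_genotypes <- function(tracts, freqs, seed = 1) {
  stopifnot(is.data.frame(tracts), is.data.frame(freqs))
  set.seed(seed)
  individuals <- unique(tracts$individual_id)
  panel_col <- c(AFR = "p_afr", EUR = "p_eur", AI = "p_ai")
  n_sites <- nrow(freqs)
  hap_names <- as.vector(t(outer(individuals, 0:1, paste, sep = "|")))
  alleles <- matrix(NA_integer_, nrow = length(hap_names), ncol = n_sites,
                    dimnames = list(hap_names, freqs$snp_id))
  lab_mat <- tract_labels_at_sites(tracts, freqs) # hap x site ancestry labels
  for (h in seq_len(nrow(alleles))) {
    labs <- lab_mat[h, ]
    if (anyNA(labs)) structural_error("a site is not covered by any tract")
    p <- numeric(n_sites)
    for (lb in c("AFR", "EUR", "AI")) {
      sel <- labs == lb
      if (any(sel)) p[sel] <- freqs[[panel_col[[lb]]]][sel]
    }
    alleles[h, ] <- as.integer(stats::runif(n_sites) < p)
  }
  out <- list(sites = freqs, alleles = alleles, individuals = individuals)
  class(out) <- "hap_genotypes"
  out
}

#' Ancestry label of each haplotype at each site
#'
#' @param tracts An `ancestry_tracts` data.frame.
#' @param sites A data.frame with `chrom` and `pos` (0-based).
#' @return A character matrix (haplotype x site) of labels; `NA` where no
#'   tract covers the site.
#' @export
tract_labels_at_sites <- function(tracts, sites) {
  individuals <- unique(tracts$individual_id)
  hap_names <- as.vector(t(outer(individuals, 0:1, paste, sep = "|")))
  lab <- matrix(NA_character_, nrow = length(hap_names), ncol = nrow(sites),
                dimnames = list(hap_names, sites$snp_id %||% NULL))
  split_key <- paste(tracts$individual_id, tracts$haplotype, sep = "|")
  tr_by_hap <- split(tracts[c("chrom", "start", "end", "label")], split_key)
  for (h in hap_names) {
    tt <- tr_by_hap[[h]]
    if (is.null(tt)) next
    for (cc in unique(sites$chrom)) {
      s_idx <- which(sites$chrom == cc)
      tc <- tt[tt$chrom == cc, ]
      if (nrow(tc) == 0) next
      tc <- tc[order(tc$start), ]
      j <- findInterval(sites$pos[s_idx], tc$start)
      ok <- j >= 1 & sites$pos[s_idx] < tc$end[pmax(j, 1)]
      lab[h, s_idx[ok]] <- tc$label[j[ok]]
    }
  }
  lab
}

#' Diploid dosage matrix from phased genotypes
#'
#' @param geno A `hap_genotypes` object.
#' @return Integer matrix (individual x site) of alternate-allele counts.
#' @export
dosage_matrix <- function(geno) {
  stopifnot(inherits(geno, "hap_genotypes"))
  a <- geno$alleles
  ind <- geno$individuals
  d <- a[paste0(ind, "|0"), , drop = FALSE] + a[paste0(ind, "|1"), , drop = FALSE]
  rownames(d) <- ind
  d
}

#' Sample allele frequencies from phased genotypes
#'
#' @param geno A `hap_genotypes` object.
#' @param individuals Optional subset of individuals.
#' @return Numeric vector of per-site alternate-allele frequencies.
#' @export
sample_allele_freqs <- function(geno, individuals = NULL) {
  a <- geno$alleles
  if (!is.null(individuals)) {
    a <- a[as.vector(t(outer(individuals, 0:1, paste, sep = "|"))), , drop = FALSE]
  }
  colMeans(a)
}
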