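# Plain-text interchange: TSV for tables, BED-like TSV for intervals,
# VCF for phased genotypes, JSON for trajectories and manifests.

#' Write / read a cohort table as TSV
#' @param cohort A cohort data.frame.
#' @param path Output file.
#' @return `read_cohort_tsv` returns a `cohort` data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in intersect(c("gender", "center", "education"), names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write / read ancestry tracts or ROH as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `individual_id`, then `haplotype`
#' and `label` for tracts or `length` for ROH; 0-based half-open.
#'
#' @param x A tracts or ROH data.frame.
#' @param path Output file.
#' @return Readers return the corresponding data.frame.
#' @export
write_tracts_tsv <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "individual_id", "haplotype",
                      "label", "length", "size_class"), names(x))
  utils::write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts_tsv
#' @export
read_tracts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cls <- if ("label" %in% names(df)) "ancestry_tracts" else "roh_segments"
  class(df) <- c(cls, "data.frame")
  df
}

#' Write / read GWAS summary statistics as TSV
#' @param records A `gwas_summary` data.frame.
#' @param path Output file.
#' @return The reader returns a `gwas_summary` data.frame.
#' @export
write_gwas_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Write phased genotypes as VCF
#'
#' Minimal VCFv4.2 with phased GT fields; positions are converted from
#' the package's 0-based convention to VCF's 1-based one. REF is `"A"`
#' and ALT `"T"` (the generator's effect allele).
#'
#' @param geno A `hap_genotypes` object.
#' @param path Output file (plain text).
#' @return Invisibly the path.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "hap_genotypes"))
  ind <- geno$individuals
  a0 <- geno$alleles[paste0(ind, "|0"), , drop = FALSE]
  a1 <- geno$alleles[paste0(ind, "|1"), , drop = FALSE]
  gt <- matrix(paste0(t(a0), "|", t(a1)), nrow = nrow(geno$sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admixdyn",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind), collapse = "\t")
  )
  body <- paste(geno$sites$chrom, geno$sites$pos + 1, geno$sites$snp_id,
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased genotypes from VCF
#'
#' Uses `vcfR` to parse the file and rebuilds the `hap_genotypes`
#' haplotype matrix (positions back to 0-based).
#'
#' @param path A VCF file with phased GT fields.
#' @return A `hap_genotypes` object (the `sites` table carries `snp_id`,
#'   `chrom`, `pos`).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  ind <- colnames(gt)
  sites <- data.frame(
    snp_id = vcfR::getID(v),
    chrom = vcfR::getCHROM(v),
    pos = vcfR::getPOS(v) - 1,
    stringsAsFactors = FALSE
  )
  hap_names <- as.vector(t(outer(ind, 0:1, paste, sep = "|")))
  alleles <- matrix(NA_integer_, nrow = length(hap_names), ncol = nrow(sites),
                    dimnames = list(hap_names, sites$snp_id))
  sp <- strsplit(as.vector(gt), "|", fixed = TRUE)
  h0 <- matrix(as.integer(vapply(sp, `[`, "", 1)), nrow = nrow(gt))
  h1 <- matrix(as.integer(vapply(sp, `[`, "", 2)), nrow = nrow(gt))
  for (i in seq_along(ind)) {
    alleles[paste0(ind[i], "|0"), ] <- h0[, i]
    alleles[paste0(ind[i], "|1"), ] <- h1[, i]
  }
  out <- list(sites = sites, alleles = alleles, individuals = ind)
  class(out) <- "hap_genotypes"
  out
}

#' Serialize / read a Moran trajectory as JSON
#' @param trajectory A `moran_trajectory`.
#' @param path Output file.
#' @return The reader returns a list mirroring the trajectory fields.
#' @export
write_trajectory_json <- function(trajectory, path) {
  x <- list(record = trajectory$record,
            parent_r = trajectory$parent_r,
            initial_mean = trajectory$initial_mean,
            final_mean = trajectory$final_mean,
            pct_change = trajectory$pct_change,
            final_size = trajectory$final_size,
            params = unclass(trajectory$params))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_json
#' @export
read_trajectory_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
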