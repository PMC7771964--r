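# Diversity within tracts: streaming pi vs brute force, F_ST arithmetic,
# tract-length regression, concordance.

# random small instance: 3 individuals, one tiny chromosome, random tract
# labels per haplotype, random alleles
random_pi_instance <- function(seed, n_ind = 3, n_sites = 40) {
  set.seed(seed)
  map <- genome_map(1000)
  ids <- sprintf("r%02d", seq_len(n_ind))
  tracts <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(0:1, function(h) {
      nb <- sample(0:3, 1)
      bounds <- sort(unique(c(0, sample(1:999, nb), 1000)))
      data.frame(individual_id = id, haplotype = h, chrom = "chr1",
                 start = bounds[-length(bounds)], end = bounds[-1],
                 label = sample(c("AFR", "EUR", "AI"), length(bounds) - 1,
                                replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  sites <- data.frame(snp_id = sprintf("s%02d", seq_len(n_sites)),
                      chrom = "chr1",
                      pos = sort(sample(0:999, n_sites)),
                      p_afr = 0.5, p_eur = 0.5, p_ai = 0.5)
  g <- generate_genotypes(tracts, sites, seed = seed + 1000)
  list(map = map, ids = ids, tracts = tracts, sites = sites, geno = g)
}

test_that("streaming pi equals the all-pairs all-sites oracle exactly", {
  for (s in 1:15) {
    inst <- random_pi_instance(s)
    lab <- tract_labels_at_sites(inst$tracts, inst$sites)
    oracle <- pi_oracle(lab, inst$geno$alleles[rownames(lab), ], "AI")
    groups <- setNames(rep("g", length(inst$ids)), inst$ids)
    out <- suppressWarnings(
      pi_within_ancestry(inst$tracts, inst$geno, groups, n_boot = 0))
    if (oracle["pairs"] == 0) {
      expect_true(is.na(out$pi))
    } else {
      expect_equal(out$n_comparisons, unname(oracle["pairs"]))
      expect_equal(out$pi, unname(oracle["diffs"] / oracle["pairs"]))
    }
  }
})

test_that("pi is zero for identical haplotypes and counts differences per site", {
  map <- genome_map(1000)
  ids <- c("a", "b")
  # hap 0 of each individual is AI; hap 1 carries EUR so only the
  # cross-individual AI pair is comparable
  tracts <- rbind(
    data.frame(individual_id = rep(ids, each = 1), haplotype = 0,
               chrom = "chr1", start = 0, end = 1000, label = "AI"),
    data.frame(individual_id = rep(ids, each = 1), haplotype = 1,
               chrom = "chr1", start = 0, end = 1000, label = "EUR"))
  sites <- data.frame(snp_id = sprintf("s%02d", 1:10), chrom = "chr1",
                      pos = seq(0, 900, by = 100),
                      p_afr = 0.5, p_eur = 0.5, p_ai = 0.5)
  alleles <- matrix(0L, nrow = 4, ncol = 10,
                    dimnames = list(c("a|0", "a|1", "b|0", "b|1"),
                                    sites$snp_id))
  geno <- structure(list(sites = sites, alleles = alleles,
                         individuals = ids), class = "hap_genotypes")
  groups <- setNames(c("g", "g"), ids)
  out <- pi_within_ancestry(tracts, geno, groups, n_boot = 0)
  expect_equal(out$pi, 0)
  expect_equal(out$n_comparisons, 10)
  # one difference over ten comparable sites
  geno$alleles["b|0", 1] <- 1L
  out1 <- pi_within_ancestry(tracts, geno, groups, n_boot = 0)
  expect_equal(out1$pi, 0.1)
})

test_that("pi approaches the generating panel heterozygosity", {
  map <- tiny_map(2, 5e6)
  coh <- manual_cohort(anc_ai = rep(1, 20))
  tr <- uniform_tracts(coh$individual_id, map, "AI")
  hets <- vapply(1:10, function(s) {
    fr <- ancestry_panel_freqs(map, n_sites = 300, fst_target = 0.1, seed = s)
    g <- generate_genotypes(tr, fr, seed = s + 100)
    groups <- setNames(rep("g", 20), coh$individual_id)
    out <- pi_within_ancestry(tr, g, groups, n_boot = 0)
    c(pi = out$pi, h = mean(2 * fr$p_ai * (1 - fr$p_ai)))
  }, numeric(2))
  expect_lt(mean(abs(hets["pi", ] - hets["h", ])), 0.01)
})

test_that("pi is invariant to individual relabeling and site order", {
  inst <- random_pi_instance(99, n_ind = 4)
  groups <- setNames(rep("g", 4), inst$ids)
  base <- pi_within_ancestry(inst$tracts, inst$geno, groups, n_boot = 0)
  # permute site order
  perm <- sample(nrow(inst$sites))
  g2 <- inst$geno
  g2$sites <- g2$sites[perm, ]
  g2$alleles <- g2$alleles[, perm]
  out2 <- pi_within_ancestry(inst$tracts, g2, groups, n_boot = 0)
  expect_equal(out2$pi, base$pi)
  # relabel individuals
  remap <- setNames(sprintf("z%02d", 4:1), inst$ids)
  tr3 <- inst$tracts
  tr3$individual_id <- remap[tr3$individual_id]
  g3 <- inst$geno
  rownames(g3$alleles) <- paste0(remap[sub("\\|[01]$", "", rownames(g3$alleles))],
                                 "|", sub("^.*\\|", "", rownames(g3$alleles)))
  g3$individuals <- unname(remap[g3$individuals])
  out3 <- pi_within_ancestry(tr3, g3, setNames(rep("g", 4), unname(remap)),
                             n_boot = 0)
  expect_equal(out3$pi, base$pi)
})

test_that("F_ST follows the printed H_T/H_S arithmetic", {
  map <- genome_map(1000)
  # 5 individuals per group, all-AI haplotypes, one site
  ids <- sprintf("i%02d", 1:10)
  tracts <- uniform_tracts(ids, map, "AI")
  sites <- data.frame(snp_id = "s1", chrom = "chr1", pos = 500,
                      p_afr = 0.5, p_eur = 0.5, p_ai = 0.5)
  make_geno <- function(count1, count2) {
    # group 1 haps: `count1` alt alleles of 10; group 2: `count2`
    alle <- matrix(0L, 20, 1, dimnames = list(
      as.vector(t(outer(ids, 0:1, paste, sep = "|"))), "s1"))
    alle[seq_len(count1), 1] <- 1L
    alle[10 + seq_len(count2), 1] <- 1L
    structure(list(sites = sites, alleles = alle, individuals = ids),
              class = "hap_genotypes")
  }
  groups <- setNames(rep(c("g1", "g2"), each = 5), ids)
  # p1 = 0.2, p2 = 0.8: H_S = 0.32, pooled p = 0.5 so H_T = 0.5, F = 0.36
  out <- fst_between_groups(tracts, make_geno(2, 8), groups)
  expect_equal(out$fst, (0.5 - 0.32) / 0.5)
  # identical frequencies: F = 0
  out0 <- fst_between_groups(tracts, make_geno(5, 5), groups)
  expect_equal(out0$fst, 0)
  # fixed difference: F = 1
  out1 <- fst_between_groups(tracts, make_geno(0, 10), groups)
  expect_equal(out1$fst, 1)
  # monomorphic comparison: undefined
  outm <- fst_between_groups(tracts, make_geno(0, 0), groups)
  expect_true(is.na(outm$fst))
})

test_that("exchangeable groups from one panel give near-zero F_ST", {
  map <- tiny_map(2, 5e6)
  coh <- manual_cohort(anc_ai = rep(1, 40))
  tr <- uniform_tracts(coh$individual_id, map, "AI")
  fr <- ancestry_panel_freqs(map, n_sites = 500, fst_target = 0.1, seed = 21)
  g <- generate_genotypes(tr, fr, seed = 22)
  groups <- setNames(rep(c("g1", "g2"), 20), coh$individual_id)
  out <- fst_between_groups(tr, g, groups, unbiased = TRUE)
  expect_lt(abs(out$fst), 0.005)
  expect_lte(out$fst, 1)
  # the uncorrected estimator carries its analytic small-sample bias of
  # about 1/(2 * haplotypes per group)
  out_raw <- fst_between_groups(tr, g, groups)
  expect_lt(abs(out_raw$fst - 1 / (2 * 40)), 0.006)
})

test_that("tract-length regression detects decade-dependent length shifts", {
  map <- genome_map(rep(1e8, 2))
  gen_tracts <- function(ids, lambda) {
    coh <- manual_cohort(anc_ai = rep(0.5, length(ids)))
    coh$individual_id <- ids
    generate_local_ancestry(coh, map, lambda_gens = lambda,
                            seed = child_seed(31, lambda))
  }
  ids_a <- sprintf("a%02d", 1:15)
  ids_b <- sprintf("b%02d", 1:15)
  decades <- setNames(rep(c(1950, 1980), each = 15), c(ids_a, ids_b))

  # identical generating process: no decade effect
  same <- rbind(gen_tracts(ids_a, 10), gen_tracts(ids_b, 10))
  fit_same <- tract_length_regression(same, decades)
  expect_gt(fit_same$coefficients["T_bin:A_dec", "p"], 0.01)
  # proportions sum to one per decade before logging
  expect_equal(unname(colSums(fit_same$f_matrix)), c(1, 1))

  # decade-dependent switch rate: strong interaction
  diff_tr <- rbind(gen_tracts(ids_a, 4), gen_tracts(ids_b, 40))
  fit_diff <- tract_length_regression(diff_tr, decades)
  expect_lt(fit_diff$coefficients["T_bin:A_dec", "p"], 0.01)
})

test_that("tract fractions track global ancestry at genome scale", {
  coh <- generate_cohort(cohort_config(n = 40, ai_concentration = 4), seed = 41)
  map <- genome_map(rep(1.3e8, 22)) # human-scale genetic length
  tr <- generate_local_ancestry(coh, map, lambda_gens = 15, seed = 42)
  cc <- tract_global_concordance(tr, coh, map = map)
  expect_gt(cor(cc$tract_fraction, cc$anc_ai), 0.99)
  # a fully AI individual has fraction exactly 1
  one <- generate_local_ancestry(manual_cohort(1), tiny_map(), seed = 43)
  cc1 <- tract_global_concordance(one, map = tiny_map())
  expect_equal(cc1$tract_fraction, 1)
})
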