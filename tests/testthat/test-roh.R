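# ROH size classes, ancestry overlap, birth-year trends.

test_that("fixed boundaries classify the canonical examples", {
  b <- fixed_class_boundaries()
  seg <- data.frame(individual_id = "x", chrom = "chr1",
                    start = 0, end = c(5e5, 1e6, 3e6),
                    length = c(5e5, 1e6, 3e6))
  out <- classify_roh(seg, b)
  expect_identical(as.character(out$size_class), c("A", "B", "C"))
  # classification partitions the segments
  expect_identical(sum(table(out$size_class)), nrow(out))
  expect_false(anyNA(out$size_class))
})

test_that("mixture-fitted boundaries separate well-separated components", {
  set.seed(1)
  x <- c(rnorm(200, 1e5, 1e4), rnorm(150, 1e6, 1e5), rnorm(100, 5e6, 4e5))
  b <- fit_class_boundaries(x)
  expect_gt(b$ab_boundary, 1.3e5)
  expect_lt(b$ab_boundary, 9e5)
  expect_gt(b$bc_boundary, 1.3e6)
  expect_lt(b$bc_boundary, 4.5e6)
  expect_identical(b$source, "fitted")
})

test_that("fitted boundaries land on the analytic responsibility crossovers", {
  # generating mixture with known parameters
  w <- c(0.5, 0.3, 0.2); mu <- c(2e5, 1.5e6, 6e6); sg <- c(5e4, 3e5, 8e5)
  set.seed(2)
  comp <- sample.int(3, 6000, replace = TRUE, prob = w)
  x <- rnorm(6000, mu[comp], sg[comp])
  b <- fit_class_boundaries(x)
  cross <- function(i, j) {
    uniroot(function(v) w[i] * dnorm(v, mu[i], sg[i]) -
              w[j] * dnorm(v, mu[j], sg[j]),
            c(mu[i], mu[j]))$root
  }
  expect_lt(abs(b$ab_boundary - cross(1, 2)) / cross(1, 2), 0.05)
  expect_lt(abs(b$bc_boundary - cross(2, 3)) / cross(2, 3), 0.05)
})

test_that("the ROH generator honours rate and mixture configuration", {
  coh <- generate_cohort(cohort_config(n = 30), seed = 3)
  map <- tiny_map(2, 5e7)
  none <- generate_roh(coh, map, roh_config(mean_segments = 0,
                                            segments_by_slope = 0), seed = 3)
  expect_identical(nrow(none), 0L)
  seg <- generate_roh(coh, map, roh_config(), seed = 4)
  expect_true(all(seg$start >= 0))
  expect_true(all(seg$end <= 5e7))
  expect_true(all(seg$length == seg$end - seg$start))
})

test_that("ancestry overlap matches the per-bp sweep oracle on random instances", {
  set.seed(5)
  chrom_len <- 2000
  map1 <- genome_map(chrom_len)
  for (k in 1:100) {
    # random tiling tracts per haplotype
    tracts <- do.call(rbind, lapply(0:1, function(h) {
      nb <- sample(0:4, 1)
      bounds <- sort(unique(c(0, sample(1:(chrom_len - 1), nb), chrom_len)))
      data.frame(individual_id = "x", haplotype = h, chrom = "chr1",
                 start = bounds[-length(bounds)], end = bounds[-1],
                 label = sample(c("AFR", "EUR", "AI"), length(bounds) - 1,
                                replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    nr <- sample(1:4, 1)
    st <- sample(0:(chrom_len - 50), nr, replace = TRUE)
    roh <- data.frame(individual_id = "x", chrom = "chr1", start = st,
                      end = pmin(chrom_len, st + sample(10:500, nr, TRUE)))
    roh$length <- roh$end - roh$start
    roh$size_class <- factor("A", levels = c("A", "B", "C"))
    rule <- sample(c("both", "mean"), 1)
    out <- overlap_by_ancestry(roh, tracts, rule = rule)
    for (lb in c("AFR", "EUR", "AI")) {
      got <- sum(out$bp[out$label == lb])
      expect_equal(got, overlap_oracle(roh, tracts, chrom_len, lb, rule))
    }
  }
})

test_that("overlaps are additive across ancestries when tracts tile", {
  coh <- generate_cohort(cohort_config(n = 10), seed = 6)
  map <- tiny_map(2, 1e7)
  tracts <- generate_local_ancestry(coh, map, seed = 6)
  seg <- classify_roh(generate_roh(coh, map, roh_config(), seed = 7),
                      fixed_class_boundaries())
  # under the mean rule, AFR+EUR+AI overlap within a size class equals the
  # (reduced) length of that class's segments
  ov <- overlap_by_ancestry(seg, tracts, rule = "mean")
  key <- paste(ov$individual_id, ov$size_class)
  per_ic <- tapply(ov$bp, key, sum)
  for (id in unique(seg$individual_id)) {
    for (cl in c("A", "B", "C")) {
      ss <- seg[seg$individual_id == id & seg$size_class == cl, ]
      if (nrow(ss) == 0) next
      red <- sum(vapply(unique(ss$chrom), function(cc) {
        r <- IRanges::reduce(IRanges::IRanges(
          start = ss$start[ss$chrom == cc] + 1, end = ss$end[ss$chrom == cc]))
        sum(IRanges::width(r))
      }, numeric(1)))
      expect_equal(unname(per_ic[paste(id, cl)]), red)
    }
  }
  # the homozygous-ancestry rule can only reduce the overlap
  ovb <- overlap_by_ancestry(seg, tracts, rule = "both")
  per_icb <- tapply(ovb$bp, paste(ovb$individual_id, ovb$size_class), sum)
  expect_true(all(per_icb <= per_ic + 1e-9))

  # individuals without ROH appear with zeros
  expect_true(all(coh$individual_id %in% ov$individual_id))

  # trivial cases: ROH inside an AI homozygous region, and disjoint from it
  tr2 <- uniform_tracts("z", map, "AI")
  seg2 <- data.frame(individual_id = "z", chrom = "chr1", start = 100,
                     end = 5000, length = 4900,
                     size_class = factor("A", levels = c("A", "B", "C")))
  ov2 <- overlap_by_ancestry(seg2, tr2)
  expect_equal(sum(ov2$bp[ov2$label == "AI"]), 4900)
  expect_equal(sum(ov2$bp[ov2$label == "EUR"]), 0)
})

test_that("Kendall trends recover the generating sign pattern", {
  # strictly increasing overlap in birth year: tau = 1
  n <- 40
  coh <- data.frame(individual_id = sprintf("i%02d", 1:n),
                    birth_year = seq(1940, 1990, length.out = n),
                    sampling_weight = 1,
                    anc_afr = 0, anc_eur = 0.5, anc_ai = 0.5)
  ov <- data.frame(individual_id = coh$individual_id, label = "AI",
                   size_class = "total_dummy", bp = seq_len(n) * 1000)
  ov$size_class <- factor("A", levels = c("A", "B", "C"))
  out <- roh_trend(ov, coh, labels = "AI")
  expect_equal(out$tau[out$size_class == "total"], 1)

  # null overlaps: tau near zero, calibrated rejection rate
  set.seed(8)
  ps <- replicate(200, {
    y <- rnorm(50)
    b <- sample(1940:1990, 50, replace = TRUE)
    suppressWarnings(cor.test(b, y, method = "kendall"))$p.value
  })
  expect_gt(mean(ps < 0.05), 0.015)
  expect_lt(mean(ps < 0.05), 0.10)

  # opposing AI/EUR trends driven by the ancestry shift
  cfg <- cohort_config(n = 400, slope_ai_per_year = 0.004,
                       ai_concentration = 40)
  cohg <- generate_cohort(cfg, seed = 9)
  map <- tiny_map(2, 2e7)
  tracts <- generate_local_ancestry(cohg, map, seed = 9)
  seg <- classify_roh(generate_roh(cohg, map,
                                   roh_config(mean_segments = 40,
                                              segments_by_slope = 0),
                                   seed = 10),
                      fixed_class_boundaries())
  ovg <- overlap_by_ancestry(seg, tracts, cohort = cohg)
  tt <- roh_trend(ovg, cohg)
  tau_ai <- tt$tau[tt$label == "AI" & tt$size_class == "total" & !tt$normalized]
  tau_eur <- tt$tau[tt$label == "EUR" & tt$size_class == "total" & !tt$normalized]
  expect_gt(tau_ai, 0)
  expect_lt(tau_eur, 0)
})

test_that("the tau-b implementation agrees with the O(n^2) counting oracle", {
  set.seed(11)
  for (k in 1:5) {
    x <- sample(1:20, 80, replace = TRUE) # plenty of ties
    y <- x + sample(-5:5, 80, replace = TRUE)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(unname(ct$estimate), kendall_oracle(x, y), tolerance = 1e-12)
  }
})
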