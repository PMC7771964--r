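# Shared fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately naive (loops, enumeration) and never share code
# with the implementation paths they check.

tiny_map <- function(n_chrom = 2, chrom_bp = 1e6) {
  genome_map(rep(chrom_bp, n_chrom))
}

# hand-built cohort rows with fixed ancestry (bypasses the generator)
manual_cohort <- function(anc_ai, anc_afr = 0 * anc_ai, birth_year = NULL) {
  n <- length(anc_ai)
  data.frame(
    individual_id = sprintf("m%03d", seq_len(n)),
    birth_year = birth_year %||% rep(1960L, n),
    sampling_weight = rep(1, n),
    anc_afr = anc_afr,
    anc_eur = 1 - anc_ai - anc_afr,
    anc_ai = anc_ai,
    stringsAsFactors = FALSE
  )
}

# one tract per chromosome per haplotype with a single label
uniform_tracts <- function(ids, map, label = "AI") {
  do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(0:1, function(h) {
      data.frame(individual_id = id, haplotype = h, chrom = map$chrom,
                 start = 0, end = map$length_bp, label = label,
                 stringsAsFactors = FALSE)
    }))
  }))
}

# OLS oracle: normal equations on an explicit design matrix
ols_oracle <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# pi oracle: loop over all haplotype pairs from distinct individuals and
# all sites; both haplotypes must carry `label` at the site
pi_oracle <- function(lab_mat, alleles, label = "AI") {
  haps <- rownames(lab_mat)
  inds <- sub("\\|[01]$", "", haps)
  diffs <- 0; pairs <- 0
  for (a in seq_along(haps)) {
    for (b in seq_len(a - 1)) {
      if (inds[a] == inds[b]) next
      for (s in seq_len(ncol(lab_mat))) {
        la <- lab_mat[a, s]; lb <- lab_mat[b, s]
        if (!is.na(la) && !is.na(lb) && la == label && lb == label) {
          pairs <- pairs + 1
          if (alleles[a, s] != alleles[b, s]) diffs <- diffs + 1
        }
      }
    }
  }
  c(diffs = diffs, pairs = pairs)
}

# Kendall tau-b oracle: O(n^2) concordant/discordant counting with ties
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# per-bp interval overlap oracle on small integer coordinates
overlap_oracle <- function(roh, tracts_ind, chrom_len, label, rule = "both") {
  covered <- rep(FALSE, chrom_len)
  for (r in seq_len(nrow(roh))) {
    covered[seq(roh$start[r] + 1, roh$end[r])] <- TRUE
  }
  hap_cov <- function(h) {
    v <- rep(FALSE, chrom_len)
    tt <- tracts_ind[tracts_ind$haplotype == h & tracts_ind$label == label, ]
    for (r in seq_len(nrow(tt))) {
      if (tt$end[r] > tt$start[r]) v[seq(tt$start[r] + 1, tt$end[r])] <- TRUE
    }
    v
  }
  h0 <- hap_cov(0); h1 <- hap_cov(1)
  if (rule == "both") sum(covered & h0 & h1)
  else (sum(covered & h0) + sum(covered & h1)) / 2
}

# PRS window-scan oracle: enumerate all 1 Mb tiles explicitly
prs_select_oracle <- function(records, p_threshold = 5e-8, window_bp = 1e6) {
  rec <- records[records$p < p_threshold, , drop = FALSE]
  keep <- c()
  for (cc in unique(rec$chrom)) {
    rc <- rec[rec$chrom == cc, ]
    for (w in unique(floor(rc$pos / window_bp))) {
      rw <- rc[floor(rc$pos / window_bp) == w, ]
      rw <- rw[order(rw$p, rw$pos), ]
      keep <- c(keep, rw$snp_id[1])
    }
  }
  out <- records[match(keep, records$snp_id), , drop = FALSE]
  out[order(out$chrom, out$pos), ]
}

# direct (H_T - H_S)/H_T on two per-site frequency vectors
fst_oracle <- function(p1, p2, n1 = NULL, n2 = NULL) {
  if (is.null(n1)) { pt <- (p1 + p2) / 2 } else { pt <- (p1 * n1 + p2 * n2) / (n1 + n2) }
  h_t <- mean(2 * pt * (1 - pt))
  h_s <- mean((2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2)
  (h_t - h_s) / h_t
}
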