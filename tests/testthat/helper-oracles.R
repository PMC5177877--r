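# Independent reference implementations used as oracles. Written directly
# from the published formulas, scalar-style, against raw genotype counts --
# deliberately a different code path from the package's vectorized routines.

# Weir & Cockerham (1984) per-site theta from per-population genotype
# counts. `counts` is an r x 3 matrix: columns (hom long, het, hom short).
oracle_wc_theta <- function(counts) {
  r <- nrow(counts)
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in seq_len(r)) {
    n[i] <- counts[i, 1] + counts[i, 2] + counts[i, 3]
    p[i] <- (2 * counts[i, 1] + counts[i, 2]) / (2 * n[i])
    h[i] <- counts[i, 2] / n[i]
  }
  nbar <- 0
  for (i in seq_len(r)) nbar <- nbar + n[i] / r
  ssq <- 0
  for (i in seq_len(r)) ssq <- ssq + n[i]^2
  nc <- (r * nbar - ssq / (r * nbar)) / (r - 1)
  pbar <- 0
  for (i in seq_len(r)) pbar <- pbar + n[i] * p[i] / (r * nbar)
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0
  for (i in seq_len(r)) hbar <- hbar + n[i] * h[i] / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Genotype counts (hom long, het, hom short) for one population at one
# locus of a phased cohort.
oracle_genotype_counts <- function(cohort, pop, locus_idx) {
  rows <- cohort$samples$population == pop
  g <- cohort$hap1[rows, locus_idx] + cohort$hap2[rows, locus_idx]
  g <- g[!is.na(g)]
  c(sum(g == 2), sum(g == 1), sum(g == 0))
}

# Brute-force re-check of the two-tier screen decision for one locus.
oracle_screen_pass <- function(cohort, locus_idx, sub_tier,
                               t_cont = 0.4, t_sub = 0.15) {
  tiers <- unique(cohort$samples$tier)
  tier_counts <- lapply(tiers, function(tt) {
    rows <- cohort$samples$tier == tt
    g <- cohort$hap1[rows, locus_idx] + cohort$hap2[rows, locus_idx]
    g <- g[!is.na(g)]
    c(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  for (i in seq_along(tiers)) {
    for (j in seq_along(tiers)) {
      if (i >= j) next
      th <- oracle_wc_theta(rbind(tier_counts[[i]], tier_counts[[j]]))
      if (is.na(th) || th <= t_cont) return(FALSE)
    }
  }
  subs <- unique(cohort$samples$population[cohort$samples$tier == sub_tier])
  sub_counts <- lapply(subs, function(pp)
    oracle_genotype_counts(cohort, pp, locus_idx))
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      if (i >= j) next
      th <- oracle_wc_theta(rbind(sub_counts[[i]], sub_counts[[j]]))
      if (is.na(th) || th <= t_sub) return(FALSE)
    }
  }
  TRUE
}

# Sequential Polya-urn evaluation of the K = 1 marginal likelihood: a
# different factorization from the package's lgamma closed form. Genotypes:
# tibble with marker_id, hap1, hap2.
oracle_lnP_K1 <- function(genotypes, lambda = 1) {
  total <- 0
  for (mid in unique(genotypes$marker_id)) {
    g <- genotypes[genotypes$marker_id == mid, ]
    alphabet <- sort(unique(c(g$hap1, g$hap2)))
    H <- length(alphabet)
    cnt <- setNames(rep(0, H), alphabet)
    C <- 0
    for (i in seq_len(nrow(g))) {
      h1 <- g$hap1[i]; h2 <- g$hap2[i]
      d1 <- (lambda + cnt[[h1]]) / (H * lambda + C)
      cnt[[h1]] <- cnt[[h1]] + 1; C <- C + 1
      d2 <- (lambda + cnt[[h2]]) / (H * lambda + C)
      cnt[[h2]] <- cnt[[h2]] + 1; C <- C + 1
      pr <- d1 * d2 * (if (h1 != h2) 2 else 1)
      total <- total + log(pr)
    }
  }
  total
}
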