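#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Each population's frequency is an independent draw from a Beta
#' distribution with mean `p` and variance `F * p * (1 - p)`, i.e. shape
#' parameters `p (1 - F) / F` and `(1 - p)(1 - F) / F`. The model is the
#' standard choice for simulating loci with a target Weir-Cockerham FST: the
#' expected per-locus theta across populations equals `F`.
#'
#' @param p Ancestral allele frequency, strictly inside (0, 1).
#' @param F Fixation index in `[0, 1)`. `F = 0` returns `p` exactly for
#'   every population (no divergence).
#' @param n_pops Number of populations to draw.
#' @return Numeric vector of `n_pops` allele frequencies.
#' @examples
#' set.seed(1)
#' draw_balding_nichols_freqs(0.5, 0.2, 5)
#' @export
draw_balding_nichols_freqs <- function(p, F, n_pops) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    abort("`p` must be a single frequency strictly inside (0, 1).")
  }
  if (F < 0 || F >= 1) abort("`F` must lie in [0, 1).")
  if (n_pops < 1L) abort("`n_pops` must be at least 1.")
  if (F == 0) return(rep(p, n_pops))
  shape <- (1 - F) / F
  rbeta(n_pops, p * shape, (1 - p) * shape)
}

# Keep Beta draws usable as downstream Balding-Nichols ancestors and as
# qnorm() arguments: rbeta can return exactly 0 or 1 when shapes are < 1.
clamp_freq <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

# Sample haplotypes for a block of loci via a Gaussian copula: loci in the
# same cluster share a latent factor with loading sqrt(r2), so long alleles
# co-occur on haplotypes while each locus keeps its marginal frequency.
# freqs: L x n_pops matrix; cluster_id: length-L (NA = isolated);
# n_hap: named vector of haplotype counts per population.
# Returns an (total haplotypes) x L 0/1 matrix, rows grouped by population.
sample_haplotypes <- function(freqs, cluster_id, n_hap, r2) {
  L <- nrow(freqs)
  H <- sum(n_hap)
  out <- matrix(0L, nrow = H, ncol = L)
  thresh <- qnorm(clamp_freq(freqs))  # L x n_pops
  pop_index <- rep(seq_along(n_hap), n_hap)
  clusters <- unique(cluster_id[!is.na(cluster_id)])
  z <- matrix(stats::rnorm(H * L), nrow = H, ncol = L)
  if (length(clusters) && r2 > 0) {
    lambda <- sqrt(r2)
    resid <- sqrt(1 - r2)
    for (cl in clusters) {
      cols <- which(!is.na(cluster_id) & cluster_id == cl)
      shared <- stats::rnorm(H)
      z[, cols] <- lambda * shared + resid * z[, cols]
    }
  }
  # allele = 1 (long) iff latent normal falls below the frequency quantile
  out[] <- (z < t(thresh)[pop_index, , drop = FALSE]) + 0L
  out
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a phased cohort with tiered population structure
#'
#' Generates phased diploid genotypes at di-allelic InDel loci under a
#' two-level Balding-Nichols hierarchy. Each locus draws an ancestral
#' frequency, then one frequency per continental tier (divergence
#' `F_continental`), then one frequency per sub-population within any
#' multi-member tier (divergence `F_sub`). Haplotypes are sampled
#' independently per chromosome, so genotypes are in Hardy-Weinberg
#' equilibrium within each population. A configurable fraction of loci is
#' laid out in tight clusters whose members share a latent haplotype
#' background (see `ld_r2` in [sim_config()]), mimicking the linkage that
#' makes multi-InDel markers multi-allelic.
#'
#' @param config A [sim_config()] object.
#' @return A `phased_cohort`: a list with `samples` (tibble: `sample_id`,
#'   `population`, `tier`), `loci` (tibble: `rsid`, `chrom`, `pos`,
#'   `short_allele`, `long_allele`, `delta`, `cluster_id`), and two
#'   haplotype matrices `hap1`, `hap2` (samples x loci, 0 = short allele,
#'   1 = long allele).
#' @export
simulate_tiered_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config

  # --- genomic layout: clusters first, then isolated loci, one walk per run
  n_clustered_target <- round(cf$cluster_fraction * cf$n_loci)
  sizes <- integer(0)
  while (sum(sizes) < n_clustered_target) {
    k <- sample(seq(cf$cluster_size_range[1], cf$cluster_size_range[2]), 1L)
    sizes <- c(sizes, min(k, cf$n_loci - sum(sizes)))
  }
  sizes <- sizes[sizes >= 2L]  # a trailing singleton is not a cluster
  n_clustered <- sum(sizes)
  n_isolated <- cf$n_loci - n_clustered
  cluster_id <- c(rep(seq_along(sizes), sizes), rep(NA_integer_, n_isolated))

  pos <- integer(cf$n_loci)
  cur <- 10000L
  i <- 1L
  for (k in sizes) {
    gaps <- sample(seq(cf$cluster_gap_range[1], cf$cluster_gap_range[2]),
                   k - 1L, replace = TRUE)
    pos[i:(i + k - 1L)] <- cur + c(0L, cumsum(gaps))
    cur <- pos[i + k - 1L] + cf$isolated_gap
    i <- i + k
  }
  if (n_isolated > 0L) {
    pos[i:cf$n_loci] <- cur + cf$isolated_gap * (seq_len(n_isolated) - 1L)
  }

  deltas <- sample(seq(cf$indel_length_range[1], cf$indel_length_range[2]),
                   cf$n_loci, replace = TRUE)
  loci <- tibble(
    rsid = sprintf("sim%05d", seq_len(cf$n_loci)),
    chrom = "1",
    pos = pos,
    short_allele = "-",
    long_allele = vapply(deltas, random_seq, character(1)),
    delta = as.integer(deltas),
    cluster_id = cluster_id
  )

  # --- allele frequencies down the hierarchy
  tiers <- cf$tier_structure
  pops <- unlist(tiers, use.names = FALSE)
  p_anc <- runif(cf$n_loci, cf$ancestral_freq_range[1], cf$ancestral_freq_range[2])
  freqs <- matrix(NA_real_, nrow = cf$n_loci, ncol = length(pops),
                  dimnames = list(NULL, pops))
  for (l in seq_len(cf$n_loci)) {
    p_tier <- clamp_freq(
      draw_balding_nichols_freqs(p_anc[l], cf$F_continental, length(tiers))
    )
    for (t in seq_along(tiers)) {
      members <- tiers[[t]]
      if (length(members) == 1L) {
        freqs[l, members] <- p_tier[t]
      } else {
        freqs[l, members] <-
          draw_balding_nichols_freqs(p_tier[t], cf$F_sub, length(members))
      }
    }
  }

  # --- phased haplotypes (two independent draws per diploid sample)
  n_per_pop <- cf$samples_per_pop
  n_samples <- sum(n_per_pop)
  h1 <- sample_haplotypes(freqs, cluster_id, n_per_pop, cf$ld_r2)
  h2 <- sample_haplotypes(freqs, cluster_id, n_per_pop, cf$ld_r2)

  pop_of_sample <- rep(names(n_per_pop), n_per_pop)
  tier_of_pop <- setNames(rep(names(tiers), lengths(tiers)), pops)
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    population = pop_of_sample,
    tier = unname(tier_of_pop[pop_of_sample])
  )
  rownames(h1) <- rownames(h2) <- samples$sample_id

  new_phased_cohort(samples, loci, h1, h2)
}

#' Simulate a two-population cohort genotyped at a multi-InDel panel
#'
#' Convenience generator for validation studies: builds `n_markers` tight
#' InDel clusters, each with its own between-population divergence drawn
#' uniformly from `theta_range`, and phased genotypes for two populations.
#' This mirrors a target-cohort design of two closely related ethnic groups
#' typed at a small ancestry-informative panel.
#'
#' @param seed Integer seed.
#' @param n_markers Number of multi-InDel markers (clusters).
#' @param marker_sizes Integer vector (recycled to `n_markers`) of member
#'   InDels per marker.
#' @param theta_range Interval from which each marker's Balding-Nichols
#'   divergence is drawn.
#' @param samples_per_pop Named vector of diploid counts, one per population.
#' @param ld_r2,cluster_gap_range,ancestral_freq_range As in [sim_config()].
#' @return A `phased_cohort` (see [simulate_tiered_cohort()]).
#' @export
simulate_panel_cohort <- function(seed,
                                  n_markers = 12L,
                                  marker_sizes = c(2L, 2L, 3L, 2L, 2L, 2L,
                                                   5L, 3L, 3L, 3L, 3L, 7L),
                                  theta_range = c(0.15, 0.4),
                                  samples_per_pop = c(TIB = 110L, HAN = 100L),
                                  ld_r2 = 0.5,
                                  cluster_gap_range = c(10L, 120L),
                                  ancestral_freq_range = c(0.1, 0.9)) {
  set.seed(seed)
  sizes <- rep_len(as.integer(marker_sizes), n_markers)
  n_loci <- sum(sizes)
  cluster_id <- rep(seq_len(n_markers), sizes)

  pos <- integer(n_loci)
  cur <- 10000L
  i <- 1L
  for (k in sizes) {
    gaps <- sample(seq(cluster_gap_range[1], cluster_gap_range[2]),
                   k - 1L, replace = TRUE)
    pos[i:(i + k - 1L)] <- cur + c(0L, cumsum(gaps))
    cur <- pos[i + k - 1L] + 10000L
    i <- i + k
  }

  F_marker <- runif(n_markers, theta_range[1], theta_range[2])
  p_anc <- runif(n_loci, ancestral_freq_range[1], ancestral_freq_range[2])
  pops <- names(samples_per_pop)
  freqs <- matrix(NA_real_, n_loci, length(pops), dimnames = list(NULL, pops))
  for (l in seq_len(n_loci)) {
    freqs[l, ] <- clamp_freq(
      draw_balding_nichols_freqs(p_anc[l], F_marker[cluster_id[l]], length(pops))
    )
  }

  deltas <- sample(1:8, n_loci, replace = TRUE)
  loci <- tibble(
    rsid = sprintf("sim%05d", seq_len(n_loci)),
    chrom = "1",
    pos = pos,
    short_allele = "-",
    long_allele = vapply(deltas, random_seq, character(1)),
    delta = as.integer(deltas),
    cluster_id = cluster_id
  )
  h1 <- sample_haplotypes(freqs, cluster_id, samples_per_pop, ld_r2)
  h2 <- sample_haplotypes(freqs, cluster_id, samples_per_pop, ld_r2)
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(sum(samples_per_pop))),
    population = rep(pops, samples_per_pop),
    tier = rep(pops, samples_per_pop)
  )
  rownames(h1) <- rownames(h2) <- samples$sample_id
  new_phased_cohort(samples, loci, h1, h2)
}
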