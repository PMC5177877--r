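# Small hand-built cohorts and genotype tables used across test files.

# Cohort from explicit haplotype matrices. loci defaults to isolated
# positions with delta 1..L.
make_cohort <- function(hap1, hap2, populations,
                        pos = NULL, deltas = NULL, cluster_id = NULL,
                        tiers = NULL) {
  n <- nrow(hap1); L <- ncol(hap1)
  if (is.null(pos)) pos <- seq(1000L, by = 10000L, length.out = L)
  if (is.null(deltas)) deltas <- rep_len(1:4, L)
  loci <- tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(L)),
    chrom = "1",
    pos = as.integer(pos),
    short_allele = "-",
    long_allele = vapply(deltas, function(d)
      paste(rep("A", d), collapse = ""), character(1)),
    delta = as.integer(deltas),
    cluster_id = if (is.null(cluster_id)) NA_integer_ else cluster_id
  )
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = populations,
    tier = if (is.null(tiers)) populations else tiers
  )
  rownames(hap1) <- rownames(hap2) <- samples$sample_id
  new_phased_cohort(samples, loci, hap1, hap2)
}

# Diploid genotype table sampled iid from known haplotype frequencies,
# for counting-convergence checks. freq_list: population -> named freq
# vector over haplotype keys.
sample_genotypes_from_freqs <- function(freq_list, n_per_pop, marker_id = "M1",
                                        seed = 1) {
  set.seed(seed)
  rows <- list()
  idx <- 0L
  for (pop in names(freq_list)) {
    f <- freq_list[[pop]]
    draws1 <- sample(names(f), n_per_pop, replace = TRUE, prob = f)
    draws2 <- sample(names(f), n_per_pop, replace = TRUE, prob = f)
    rows[[pop]] <- tibble::tibble(
      sample_id = sprintf("%s%04d", pop, idx + seq_len(n_per_pop)),
      population = pop,
      marker_id = marker_id,
      hap1 = pmin(draws1, draws2),
      hap2 = pmax(draws1, draws2)
    )
    idx <- idx + n_per_pop
  }
  dplyr::bind_rows(rows)
}

# A cohort with 12 rule-compliant planted 2-3 locus clusters plus decoys
# that each violate one formation rule. 40 diploid samples, one population.
make_planted_cohort <- function(seed = 42) {
  set.seed(seed)
  n <- 40L
  loci <- list()
  planted_sets <- list()
  pos_cursor <- 10000L
  add_locus <- function(gap, delta) {
    pos_cursor <<- pos_cursor + gap
    list(pos = pos_cursor, delta = delta)
  }
  spec_rows <- list()
  # 12 compliant clusters: alternating 2- and 3-locus, gaps 40-80, deltas
  # distinct powers so size maps are injective
  for (k in 1:12) {
    size <- if (k %% 2 == 0) 3L else 2L
    members <- list(add_locus(10000L, 1L))
    for (j in seq_len(size - 1L)) {
      members <- c(members, list(add_locus(40L + 10L * j, 2L^j)))
    }
    spec_rows[[length(spec_rows) + 1L]] <-
      list(type = "planted", members = members)
  }
  # decoy A: pair 400 bp apart (violates spacing -> two discarded singletons)
  spec_rows[[length(spec_rows) + 1L]] <- list(
    type = "decoy_gap",
    members = list(add_locus(10000L, 1L), add_locus(400L, 2L)))
  # decoy B: tight pair, monomorphic all-short (violates >= 2 haplotypes)
  spec_rows[[length(spec_rows) + 1L]] <- list(
    type = "decoy_mono",
    members = list(add_locus(10000L, 1L), add_locus(50L, 2L)))
  # decoy C: tight pair whose span forces the amplicon over the cap
  spec_rows[[length(spec_rows) + 1L]] <- list(
    type = "decoy_len",
    members = list(add_locus(10000L, 1L), add_locus(245L, 2L)))
  # decoy D: equal deltas with all four haplotypes observed (size collision)
  spec_rows[[length(spec_rows) + 1L]] <- list(
    type = "decoy_collide",
    members = list(add_locus(10000L, 2L), add_locus(50L, 2L)))

  all_pos <- integer(); all_delta <- integer(); type_of <- character()
  group_of <- integer()
  for (gi in seq_along(spec_rows)) {
    for (mem in spec_rows[[gi]]$members) {
      all_pos <- c(all_pos, mem$pos)
      all_delta <- c(all_delta, mem$delta)
      type_of <- c(type_of, spec_rows[[gi]]$type)
      group_of <- c(group_of, gi)
    }
  }
  L <- length(all_pos)
  hap <- function() {
    m <- matrix(0L, n, L)
    for (gi in seq_along(spec_rows)) {
      cols <- which(group_of == gi)
      ty <- type_of[cols[1]]
      if (ty == "decoy_mono") next  # stays all-short
      k <- length(cols)
      # draw per-chromosome patterns from {all-short, first-long, all-long}
      patt <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
      for (ci in seq_along(cols)) {
        m[, cols[ci]] <- ifelse(patt == 2L, 1L,
                                ifelse(patt == 1L & ci == 1L, 1L, 0L))
      }
      if (ty == "decoy_collide") {
        # force all four 2-locus haplotypes onto some chromosomes
        m[1, cols] <- c(0L, 1L)
        m[2, cols] <- c(1L, 0L)
        m[3, cols] <- c(1L, 1L)
        m[4, cols] <- c(0L, 0L)
      }
    }
    m
  }
  make_cohort(hap(), hap(), rep("POP", n), pos = all_pos, deltas = all_delta,
              cluster_id = group_of)
}

# Two-population marker genotype table with disjoint haplotypes at every
# marker (perfectly separable).
make_separable_genotypes <- function(n_a = 30, n_b = 30, n_markers = 12) {
  rows <- list()
  for (m in seq_len(n_markers)) {
    mid <- sprintf("M%02d", m)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("A%03d", seq_len(n_a)),
      population = "A", marker_id = mid, hap1 = "00", hap2 = "00")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("B%03d", seq_len(n_b)),
      population = "B", marker_id = mid, hap1 = "11", hap2 = "11")
  }
  dplyr::bind_rows(rows)
}
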