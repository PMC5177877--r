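#' Simulation configuration for hierarchical InDel cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_tiered_cohort()]. The defaults emulate a 1000-Genomes-like
#' two-level population structure: five continental groups with high
#' divergence, one of which (the East-Asian analog) is subdivided into five
#' sub-populations with low divergence.
#'
#' @param seed Integer seed; every random draw in the simulator flows from it.
#' @param n_loci Number of di-allelic InDel loci to simulate.
#' @param tier_structure Named list mapping each continental tier to the
#'   character vector of its member population labels. Tiers with more than
#'   one member are subdivided using `F_sub`.
#' @param F_continental Fixation index in `[0, 1)` governing divergence
#'   between continental tiers (Balding-Nichols model).
#' @param F_sub Fixation index in `[0, 1)` governing divergence among
#'   sub-populations within a multi-member tier.
#' @param samples_per_pop Diploid sample count per population; a single count
#'   or a named vector keyed by population label.
#' @param ancestral_freq_range Interval strictly inside `(0, 1)` from which
#'   each locus's ancestral long-allele frequency is drawn uniformly.
#' @param cluster_fraction Fraction of loci placed in tight genomic clusters
#'   (the raw material for multi-InDel markers); the rest are isolated.
#' @param cluster_gap_range Base-pair interval for the gap between adjacent
#'   loci within a cluster. Set its upper bound above 250 to exercise the
#'   spacing filter in both directions.
#' @param cluster_size_range Integer interval for the number of loci per
#'   cluster.
#' @param indel_length_range Integer interval (bp) for the long-minus-short
#'   allele length difference at each locus.
#' @param ld_r2 Squared latent correlation shared by loci in one cluster, so
#'   clustered markers show more than two but usually fewer than `2^k`
#'   haplotypes.
#' @param isolated_gap Base-pair spacing between consecutive isolated loci
#'   (and between clusters), chosen large enough that no two units can be
#'   chained by the 250-bp rule.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_tiered_cohort()]
#' @export
sim_config <- function(seed,
                       n_loci = 1000L,
                       tier_structure = list(
                         AFR = "AFR",
                         EAS = c("CHS", "CHB", "JPT", "KHV", "CDX"),
                         EUR = "EUR",
                         SAS = "SAS",
                         AMR = "AMR"
                       ),
                       F_continental = 0.15,
                       F_sub = 0.02,
                       samples_per_pop = 100L,
                       ancestral_freq_range = c(0.05, 0.95),
                       cluster_fraction = 0.3,
                       cluster_gap_range = c(10L, 240L),
                       cluster_size_range = c(2L, 7L),
                       indel_length_range = c(1L, 8L),
                       ld_r2 = 0.5,
                       isolated_gap = 10000L) {
  if (length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.")
  }
  if (n_loci < 1L) abort("`n_loci` must be at least 1.")
  if (!is.list(tier_structure) || is.null(names(tier_structure)) ||
      any(names(tier_structure) == "")) {
    abort("`tier_structure` must be a named list of population-label vectors.")
  }
  pops <- unlist(tier_structure, use.names = FALSE)
  if (anyDuplicated(pops)) abort("population labels must be unique across tiers.")
  for (F in c(F_continental = F_continental, F_sub = F_sub)) {
    if (F < 0 || F >= 1) abort("fixation indices must lie in [0, 1).")
  }
  if (length(samples_per_pop) == 1L && is.null(names(samples_per_pop))) {
    samples_per_pop <- setNames(rep(as.integer(samples_per_pop), length(pops)), pops)
  }
  if (!all(pops %in% names(samples_per_pop))) {
    abort("`samples_per_pop` must cover every population label.")
  }
  if (any(samples_per_pop < 1L)) abort("`samples_per_pop` must be positive.")
  check_interval <- function(x, name, lo, hi, strict = FALSE) {
    ok <- length(x) == 2L && x[1] <= x[2] &&
      (if (strict) x[1] > lo && x[2] < hi else x[1] >= lo && x[2] <= hi)
    if (!ok) abort(sprintf("`%s` must be an ordered interval within %s%g, %g%s.",
                           name, if (strict) "(" else "[", lo, hi,
                           if (strict) ")" else "]"))
  }
  check_interval(ancestral_freq_range, "ancestral_freq_range", 0, 1, strict = TRUE)
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    abort("`cluster_fraction` must lie in [0, 1].")
  }
  check_interval(cluster_gap_range, "cluster_gap_range", 1, Inf)
  check_interval(cluster_size_range, "cluster_size_range", 2, Inf)
  check_interval(indel_length_range, "indel_length_range", 1, Inf)
  if (ld_r2 < 0 || ld_r2 > 1) abort("`ld_r2` must lie in [0, 1].")

  structure(
    list(
      seed = as.integer(seed),
      n_loci = as.integer(n_loci),
      tier_structure = tier_structure,
      F_continental = F_continental,
      F_sub = F_sub,
      samples_per_pop = samples_per_pop[pops],
      ancestral_freq_range = ancestral_freq_range,
      cluster_fraction = cluster_fraction,
      cluster_gap_range = as.integer(cluster_gap_range),
      cluster_size_range = as.integer(cluster_size_range),
      indel_length_range = as.integer(indel_length_range),
      ld_r2 = ld_r2,
      isolated_gap = as.integer(isolated_gap)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  pops <- unlist(x$tier_structure, use.names = FALSE)
  cat("<sim_config>\n")
  cat(sprintf("  %d loci, %d tiers, %d populations, %d samples\n",
              x$n_loci, length(x$tier_structure), length(pops),
              sum(x$samples_per_pop)))
  cat(sprintf("  F_continental = %g, F_sub = %g, cluster_fraction = %g\n",
              x$F_continental, x$F_sub, x$cluster_fraction))
  invisible(x)
}
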