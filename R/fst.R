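#' Per-site Weir-Cockerham theta
#'
#' Estimates the fixation index FST at one di-allelic locus from
#' per-population summary statistics, using the variance-component
#' estimator of Weir and Cockerham (1984): among-population (`a`),
#' among-individual-within-population (`b`) and within-individual (`c`)
#' components, with `theta = a / (a + b + c)`. Sampling can make the
#' estimate slightly negative; it is reported unclamped. When every
#' population is fixed for the same allele all components vanish and the
#' estimator is undefined (`NA` with reason `"monomorphic"`).
#'
#' @param n Diploid sample sizes per population (length two or more).
#' @param p Long-allele frequencies per population.
#' @param h Observed heterozygote proportions per population.
#' @return A single numeric theta, or `NA` with attribute `reason`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @examples
#' wc_theta(n = c(10, 10), p = c(1, 0), h = c(0, 0))  # fixed difference: 1
#' @export
wc_theta <- function(n, p, h) {
  r <- length(n)
  if (r < 2L || length(p) != r || length(h) != r) {
    abort("`n`, `p`, `h` must have equal length >= 2.")
  }
  if (any(n < 1) || any(p < 0 | p > 1) || any(h < 0 | h > 1)) {
    abort("need n >= 1, p in [0,1], h in [0,1].")
  }
  comp <- wc_components(n, p, h)
  denom <- comp$a + comp$b + comp$c
  if (denom == 0) {
    return(structure(NA_real_, reason = "monomorphic"))
  }
  comp$a / denom
}

#' Multi-locus Weir-Cockerham theta
#'
#' Combines loci the way Weir and Cockerham prescribe for genome-scale
#' estimates: variance components are summed over loci before taking the
#' ratio, `theta = sum(a) / sum(a + b + c)`. Unlike the mean of per-locus
#' ratios (which is biased downward by the ratio's nonlinearity), this
#' estimator recovers the generating fixation index of a Balding-Nichols
#' simulation.
#'
#' @param stats Tibble from [locus_pop_stats()] (columns `rsid`,
#'   `population`, `n`, `p`, `h`).
#' @return A single numeric theta.
#' @export
wc_theta_multilocus <- function(stats) {
  pops <- sort(unique(stats$population))
  if (length(pops) < 2L) abort("need at least two populations.")
  by_pop <- split(stats, stats$population)
  ids <- by_pop[[1]]$rsid
  for (b in by_pop) {
    if (!identical(b$rsid, ids)) abort("populations disagree on the locus set.")
  }
  n <- do.call(cbind, lapply(by_pop, `[[`, "n"))
  p <- do.call(cbind, lapply(by_pop, `[[`, "p"))
  h <- do.call(cbind, lapply(by_pop, `[[`, "h"))
  comp <- wc_components(n, p, h)
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

# Variance components; all arguments may be L x r matrices for a vectorized
# sweep over loci (rows), or plain vectors for a single locus.
wc_components <- function(n, p, h) {
  if (!is.matrix(n)) {
    n <- matrix(n, nrow = 1L)
    p <- matrix(p, nrow = 1L)
    h <- matrix(h, nrow = 1L)
  }
  r <- ncol(n)
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Per-locus pairwise theta between all population pairs
#'
#' Computes the two-population Weir-Cockerham theta at every locus for every
#' unordered pair of population labels, either at the sub-population level
#' (`group = "population"`) or pooling samples to continental tiers
#' (`group = "tier"`). The implicit matrix is symmetric with an empty
#' diagonal; only the upper triangle is materialised.
#'
#' @param cohort A `phased_cohort`.
#' @param group Label column used as the population unit.
#' @param populations Optional subset of labels (default: all).
#' @return Tibble with columns `rsid`, `chrom`, `pos`, `pop_a`, `pop_b`,
#'   `theta`, `reason` (`NA` when theta is defined).
#' @export
pairwise_theta <- function(cohort, group = c("population", "tier"),
                           populations = NULL) {
  group <- match.arg(group)
  stats <- locus_pop_stats(cohort, group = group)
  pops <- unique(stats$population)
  if (!is.null(populations)) {
    missing_pops <- setdiff(populations, pops)
    if (length(missing_pops)) {
      abort(paste("populations not in cohort:",
                  paste(missing_pops, collapse = ", ")))
    }
    pops <- populations
  }
  counts <- cohort$samples[[if (group == "tier") "tier" else "population"]]
  if (any(!table(factor(counts, levels = pops)))) {
    abort("every population must have at least one sample.")
  }
  if (length(pops) < 2L) abort("need at least two populations.")
  by_pop <- split(stats, stats$population)
  loci_info <- by_pop[[pops[1]]][c("rsid", "chrom", "pos")]
  pairs <- utils::combn(pops, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- by_pop[[pairs[1L, j]]]
    b <- by_pop[[pairs[2L, j]]]
    n <- cbind(a$n, b$n)
    p <- cbind(a$p, b$p)
    h <- cbind(a$h, b$h)
    comp <- wc_components(n, p, h)
    denom <- comp$a + comp$b + comp$c
    theta <- ifelse(denom == 0, NA_real_, comp$a / denom)
    tibble(
      rsid = loci_info$rsid, chrom = loci_info$chrom, pos = loci_info$pos,
      pop_a = pairs[1L, j], pop_b = pairs[2L, j],
      theta = theta,
      reason = ifelse(denom == 0, "monomorphic", NA_character_)
    )
  })
  bind_rows(out)
}

#' Two-tier FST screen for candidate ancestry-informative InDels
#'
#' Applies the tiered nomination rule: a locus passes iff its
#' Weir-Cockerham theta exceeds `t_continental` for every pair of
#' continental groups *and* exceeds `t_sub` for every pair of
#' sub-populations within the focal continental group. Both inequalities
#' are strict. A locus with any undefined pairwise theta fails with that
#' reason.
#'
#' @param cohort A `phased_cohort` whose sample table carries both a
#'   `tier` (continental) and a `population` (sub-population) label.
#' @param sub_tier Name of the tier whose member sub-populations are
#'   compared under `t_sub`.
#' @param t_continental,t_sub Strict lower thresholds on pairwise theta.
#' @return Tibble with one row per locus: `rsid`, `chrom`, `pos`,
#'   `min_continental_theta`, `min_sub_theta`, `pass`, `reason`; passing
#'   loci first, sorted by `min_continental_theta` descending (ties by
#'   chromosome, position).
#' @export
screen_loci <- function(cohort, sub_tier = "EAS",
                        t_continental = 0.4, t_sub = 0.15) {
  cont <- pairwise_theta(cohort, group = "tier")
  sub_pops <- unique(cohort$samples$population[cohort$samples$tier == sub_tier])
  if (length(sub_pops) < 2L) {
    abort(sprintf("tier %s has fewer than two sub-populations.", sub_tier))
  }
  sub_cohort <- subset_cohort(cohort, cohort$samples$tier == sub_tier)
  sub <- pairwise_theta(sub_cohort, group = "population")
  screen_from_theta(cont, sub, t_continental, t_sub)
}

# Core screen on precomputed pairwise-theta tables (exposed for testing the
# rule independently of the estimator).
screen_from_theta <- function(continental, sub, t_continental = 0.4,
                              t_sub = 0.15) {
  summarise_tier <- function(tt, thresh, label) {
    tt %>%
      group_by(.data$rsid, .data$chrom, .data$pos) %>%
      summarise(
        min_theta = if (anyNA(.data$theta)) NA_real_ else min(.data$theta),
        worst = {
          i <- if (anyNA(.data$theta)) which(is.na(.data$theta))[1]
               else which.min(.data$theta)
          sprintf("%s pair %s-%s %s", label,
                  .data$pop_a[i], .data$pop_b[i],
                  ifelse(is.na(.data$theta[i]), "monomorphic",
                         sprintf("theta=%.4g <= %g", .data$theta[i], thresh)))
        },
        .groups = "drop"
      )
  }
  cs <- summarise_tier(continental, t_continental, "continental")
  ss <- summarise_tier(sub, t_sub, "sub")
  joined <- left_join(cs, ss, by = c("rsid", "chrom", "pos"),
                      suffix = c("_cont", "_sub"))
  pass_cont <- !is.na(joined$min_theta_cont) & joined$min_theta_cont > t_continental
  pass_sub <- !is.na(joined$min_theta_sub) & joined$min_theta_sub > t_sub
  reason <- rep(NA_character_, nrow(joined))
  reason[!pass_cont] <- joined$worst_cont[!pass_cont]
  reason[pass_cont & !pass_sub] <- joined$worst_sub[pass_cont & !pass_sub]
  out <- tibble(
    rsid = joined$rsid, chrom = joined$chrom, pos = joined$pos,
    min_continental_theta = joined$min_theta_cont,
    min_sub_theta = joined$min_theta_sub,
    pass = pass_cont & pass_sub,
    reason = reason
  )
  out[order(-out$pass, -replace(out$min_continental_theta,
                                is.na(out$min_continental_theta), -Inf),
            out$chrom, out$pos), ]
}

#' Restrict a cohort to a subset of samples and/or loci
#'
#' @param cohort A `phased_cohort`.
#' @param sample_keep Logical or index vector over samples.
#' @param locus_keep Logical or index vector over loci.
#' @return A `phased_cohort`.
#' @export
subset_cohort <- function(cohort, sample_keep = NULL, locus_keep = NULL) {
  if (is.null(sample_keep)) sample_keep <- seq_len(nrow(cohort$samples))
  if (is.null(locus_keep)) locus_keep <- seq_len(nrow(cohort$loci))
  new_phased_cohort(
    cohort$samples[sample_keep, , drop = FALSE],
    cohort$loci[locus_keep, , drop = FALSE],
    cohort$hap1[sample_keep, locus_keep, drop = FALSE],
    cohort$hap2[sample_keep, locus_keep, drop = FALSE]
  )
}
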