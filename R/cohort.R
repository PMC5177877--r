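#' Construct a phased cohort
#'
#' The container for phased diploid InDel genotypes. Allele states are coded
#' 0 (short allele) and 1 (long allele); each sample carries two haplotype
#' vectors over the loci. Loci must be sorted by (chromosome, position) with
#' no duplicate positions on a chromosome.
#'
#' @param samples Tibble with columns `sample_id`, `population` and
#'   optionally `tier` (defaults to `population`).
#' @param loci Tibble with columns `rsid`, `chrom`, `pos`, `short_allele`,
#'   `long_allele`, `delta`.
#' @param hap1,hap2 Integer 0/1 matrices, samples x loci.
#' @return An object of class `phased_cohort`.
#' @export
new_phased_cohort <- function(samples, loci, hap1, hap2) {
  samples <- as_tibble(samples)
  loci <- as_tibble(loci)
  if (!"tier" %in% names(samples)) samples$tier <- samples$population
  need_s <- c("sample_id", "population", "tier")
  need_l <- c("rsid", "chrom", "pos", "short_allele", "long_allele", "delta")
  if (!all(need_s %in% names(samples))) {
    abort("`samples` needs columns sample_id, population.")
  }
  if (!all(need_l %in% names(loci))) {
    abort(paste("`loci` needs columns", paste(need_l, collapse = ", "), "."))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids.")
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci)))) {
    abort("`loci` must be sorted by (chrom, pos).")
  }
  if (any(duplicated(loci[c("chrom", "pos")]))) {
    abort("duplicate locus positions on one chromosome.")
  }
  if (any(loci$pos < 1L)) abort("positions must be >= 1.")
  if (any(loci$delta <= 0L)) abort("`delta` must be positive at every locus.")
  for (h in list(hap1, hap2)) {
    if (!is.matrix(h) || nrow(h) != nrow(samples) || ncol(h) != nrow(loci)) {
      abort("haplotype matrices must be samples x loci.")
    }
    vals <- h[!is.na(h)]
    if (length(vals) && !all(vals %in% c(0L, 1L))) {
      abort("haplotype states must be 0 (short) or 1 (long), or NA.")
    }
  }
  dimnames(hap1) <- list(samples$sample_id, NULL)
  dimnames(hap2) <- list(samples$sample_id, NULL)
  structure(
    list(samples = samples, loci = loci,
         hap1 = hap1, hap2 = hap2),
    class = "phased_cohort"
  )
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("<phased_cohort> %d samples x %d loci\n",
              nrow(x$samples), nrow(x$loci)))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Per-locus per-population genotype summary statistics
#'
#' Reduces a phased cohort to the sufficient statistics of the per-site
#' Weir-Cockerham estimator: diploid sample size, long-allele frequency and
#' observed heterozygote proportion, per locus and population grouping.
#' Samples with a missing allele at a locus are excluded locus-wise.
#'
#' @param cohort A `phased_cohort`.
#' @param group Grouping column of `cohort$samples` to treat as the
#'   population label: `"population"` or `"tier"`.
#' @return Tibble with columns `rsid`, `chrom`, `pos`, `population`, `n`,
#'   `p`, `h`.
#' @export
locus_pop_stats <- function(cohort, group = c("population", "tier")) {
  group <- match.arg(group)
  labels <- cohort$samples[[group]]
  g <- cohort$hap1 + cohort$hap2            # dosage 0/1/2, NA if unphased
  het <- (cohort$hap1 != cohort$hap2) + 0L
  out <- lapply(unique(labels), function(pop) {
    rows <- labels == pop
    n_eff <- colSums(!is.na(g[rows, , drop = FALSE]))
    tibble(
      rsid = cohort$loci$rsid,
      chrom = cohort$loci$chrom,
      pos = cohort$loci$pos,
      population = pop,
      n = n_eff,
      p = colSums(g[rows, , drop = FALSE], na.rm = TRUE) / (2 * pmax(n_eff, 1L)),
      h = colSums(het[rows, , drop = FALSE], na.rm = TRUE) / pmax(n_eff, 1L)
    )
  })
  bind_rows(out)
}
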