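#' Per-marker haplotype pairs from phased genotypes
#'
#' For every sample and marker, restricts the sample's two phased
#' allele-state vectors to the marker's member loci, giving the unordered
#' haplotype pair a CE assay would observe. Samples with a missing allele
#' at any member locus are dropped at that marker.
#'
#' @param cohort A `phased_cohort`.
#' @param panel An `indel_panel`.
#' @return Tibble with columns `sample_id`, `population`, `marker_id`,
#'   `hap1`, `hap2` (allele-state strings, sorted so `hap1 <= hap2`).
#' @export
marker_genotypes <- function(cohort, panel) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    m <- panel$loci[[i]]
    idx <- match(m$rsid, cohort$loci$rsid)
    if (anyNA(idx)) {
      abort(paste("member loci absent from cohort:",
                  paste(m$rsid[is.na(idx)], collapse = ", ")))
    }
    h1 <- cohort$hap1[, idx, drop = FALSE]
    h2 <- cohort$hap2[, idx, drop = FALSE]
    ok <- !rowSums(is.na(h1)) & !rowSums(is.na(h2))
    if (any(!ok)) {
      inform(sprintf("marker %s: dropped %d sample(s) with missing phase.",
                     panel$marker_id[i], sum(!ok)))
    }
    s1 <- unname(apply(h1[ok, , drop = FALSE], 1L, paste, collapse = ""))
    s2 <- unname(apply(h2[ok, , drop = FALSE], 1L, paste, collapse = ""))
    tibble(
      sample_id = cohort$samples$sample_id[ok],
      population = cohort$samples$population[ok],
      marker_id = panel$marker_id[i],
      hap1 = pmin(s1, s2),
      hap2 = pmax(s1, s2)
    )
  })
  bind_rows(out)
}

size_lookup <- function(panel, marker_id) {
  sm <- panel$size_map[[match(marker_id, panel$marker_id)]]
  if (is.null(sm)) {
    abort(sprintf("marker %s has no size map (base size unknown).", marker_id))
  }
  setNames(sm$size, sm$haplotype)
}

#' CE peak sets for marker genotypes
#'
#' Maps each haplotype pair through the marker's amplicon-size map: a
#' heterozygote shows two peaks, a homozygote one. Markers whose size map
#' collides on the haplotypes present in the input are refused, since their
#' electropherograms would not identify the genotype.
#'
#' @param genotypes Tibble from [marker_genotypes()] (allele-state keys).
#' @param panel An `indel_panel` with size maps.
#' @return The input with `size1`, `size2` (bp, `size1 <= size2`) and
#'   `n_peaks` (1 or 2) columns added.
#' @export
ce_peaks <- function(genotypes, panel) {
  out <- lapply(split(genotypes, genotypes$marker_id), function(g) {
    mid <- g$marker_id[1]
    lut <- size_lookup(panel, mid)
    present <- unique(c(g$hap1, g$hap2))
    sm <- panel$size_map[[match(mid, panel$marker_id)]]
    if (nrow(check_size_degeneracy(sm, present)) > 0L) {
      abort(sprintf(
        "marker %s: amplicon sizes are degenerate over observed haplotypes.",
        mid))
    }
    unknown <- setdiff(present, names(lut))
    if (length(unknown)) {
      abort(sprintf("marker %s: haplotype %s not in size map.",
                    mid, unknown[1]))
    }
    s1 <- unname(lut[g$hap1])
    s2 <- unname(lut[g$hap2])
    mutate(g, size1 = pmin(s1, s2), size2 = pmax(s1, s2),
           n_peaks = 1L + (s1 != s2))
  })
  bind_rows(out)
}

#' Call marker genotypes from CE peak sizes
#'
#' Inverse of the amplicon-size encoding: one peak calls a homozygote, two
#' peaks the heterozygote of the two size pre-images. Valid for any size in
#' the map, including haplotypes never seen in training data.
#'
#' @param peaks Tibble with columns `marker_id`, `size1`, `size2` (`size2`
#'   equal to `size1` or `NA` for a single peak). More than two distinct
#'   sizes per row is a mixture/artifact error; a size absent from the map
#'   is an off-ladder error.
#' @param panel An `indel_panel` with size maps.
#' @return Tibble with `marker_id`, `hap1`, `hap2` (and any id columns of
#'   the input), haplotypes sorted within the pair.
#' @export
call_genotypes_from_peaks <- function(peaks, panel) {
  if (!all(c("marker_id", "size1", "size2") %in% names(peaks))) {
    abort("`peaks` needs columns marker_id, size1, size2.")
  }
  extra <- any(!is.na(peaks$size2) & !is.na(peaks$size1) &
                 peaks$size2 < peaks$size1)
  if (extra) abort("peak sizes must satisfy size1 <= size2.")
  out <- lapply(split(peaks, peaks$marker_id), function(g) {
    mid <- g$marker_id[1]
    lut <- size_lookup(panel, mid)
    if (anyDuplicated(lut)) {
      abort(sprintf("marker %s: size map is degenerate; cannot call.", mid))
    }
    inv <- setNames(names(lut), as.character(lut))
    s2 <- ifelse(is.na(g$size2), g$size1, g$size2)
    for (s in unique(c(g$size1, s2))) {
      if (!as.character(s) %in% names(inv)) {
        abort(sprintf("marker %s: off-ladder peak at %g bp.", mid, s))
      }
    }
    h1 <- unname(inv[as.character(g$size1)])
    h2 <- unname(inv[as.character(s2)])
    mutate(g, hap1 = pmin(h1, h2), hap2 = pmax(h1, h2))
  })
  bind_rows(out)
}

#' Haplotype frequencies by counting
#'
#' Per marker and population, the frequency of each haplotype is the number
#' of chromosomes carrying it divided by twice the number of fully typed
#' samples — plain maximum-likelihood counting with no smoothing
#' (pseudocounts are the classifier's concern). Haplotypes observed in any
#' population of a marker get an explicit (possibly zero) row in every
#' population, so downstream tables keep a common column set.
#'
#' @param genotypes Tibble with `sample_id`, `population`, `marker_id`,
#'   `hap1`, `hap2` (any consistent key namespace).
#' @return Tibble with `marker_id`, `population`, `haplotype`, `count`,
#'   `n_chrom`, `frequency`; `frequency` sums to 1 within each
#'   marker-population row group.
#' @export
count_haplotype_frequencies <- function(genotypes) {
  g <- genotypes[!is.na(genotypes$hap1) & !is.na(genotypes$hap2), , drop = FALSE]
  lost <- genotypes %>% distinct(.data$marker_id, .data$population) %>%
    dplyr::anti_join(g %>% distinct(.data$marker_id, .data$population),
                     by = c("marker_id", "population"))
  if (nrow(lost)) {
    warn(sprintf("%d marker-population group(s) had no typed samples; rows omitted.",
                 nrow(lost)))
  }
  long <- bind_rows(
    g %>% select("marker_id", "population", haplotype = "hap1"),
    g %>% select("marker_id", "population", haplotype = "hap2")
  )
  counts <- long %>%
    count(.data$marker_id, .data$population, .data$haplotype, name = "count") %>%
    group_by(.data$marker_id) %>%
    tidyr::complete(.data$population, .data$haplotype,
                    fill = list(count = 0L)) %>%
    ungroup()
  counts %>%
    group_by(.data$marker_id, .data$population) %>%
    mutate(n_chrom = sum(.data$count),
           frequency = .data$count / .data$n_chrom) %>%
    ungroup() %>%
    arrange(.data$marker_id, .data$population, .data$haplotype)
}

#' Convert allele-state genotype keys to amplicon-size keys
#'
#' @param genotypes Tibble from [marker_genotypes()].
#' @param panel An `indel_panel` with size maps.
#' @return The same tibble with `hap1`, `hap2` re-keyed as amplicon sizes
#'   (characters), sorted within the pair.
#' @export
genotypes_to_sizes <- function(genotypes, panel) {
  sized <- ce_peaks(genotypes, panel)
  sized %>%
    mutate(hap1 = as.character(.data$size1), hap2 = as.character(.data$size2)) %>%
    select(-"size1", -"size2", -"n_peaks")
}
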