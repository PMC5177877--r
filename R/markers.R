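#' Greedy clustering of screened loci into candidate markers
#'
#' Scans loci in (chromosome, position) order and chains a locus onto the
#' current group iff it sits on the same chromosome within `max_gap` bp of
#' the previous member (adjacent-pair gap, not total span — a marker may
#' span more than `max_gap` as long as every adjacent gap is below it).
#' Groups of size 1 are discarded: a multi-InDel needs at least two members.
#'
#' @param loci Tibble with columns `rsid`, `chrom`, `pos` (any extra columns
#'   are carried through). Re-sorted internally.
#' @param max_gap Strict upper bound (bp) on the adjacent-pair gap.
#' @return The grouped loci with a `candidate_id` column; loci not in any
#'   group are absent.
#' @export
cluster_candidates <- function(loci, max_gap = 250) {
  loci <- as_tibble(loci)[order(loci$chrom, loci$pos), ]
  n <- nrow(loci)
  if (n == 0L) return(mutate(loci, candidate_id = integer()))
  new_group <- c(TRUE, loci$chrom[-1] != loci$chrom[-n] |
                         diff(loci$pos) >= max_gap)
  gid <- cumsum(new_group)
  keep <- gid %in% which(tabulate(gid) >= 2L)
  out <- loci[keep, , drop = FALSE]
  out$candidate_id <- match(gid[keep], unique(gid[keep]))
  out
}

#' Observed haplotypes of a marker in a phased cohort
#'
#' Restricts every sample's two phased allele-state vectors to the marker's
#' member loci and tallies the distinct haplotypes. Chromosomes from samples
#' with a missing allele at any member locus are excluded.
#'
#' @param cohort A `phased_cohort`.
#' @param marker_loci Tibble of member loci (matched into the cohort by
#'   `rsid`).
#' @return Tibble with columns `haplotype` (allele-state string) and
#'   `count`, sorted by decreasing count. Counts sum to twice the number of
#'   fully typed samples.
#' @export
enumerate_haplotypes <- function(cohort, marker_loci) {
  idx <- match(marker_loci$rsid, cohort$loci$rsid)
  if (anyNA(idx)) {
    abort(paste("member loci absent from cohort:",
                paste(marker_loci$rsid[is.na(idx)], collapse = ", ")))
  }
  h1 <- cohort$hap1[, idx, drop = FALSE]
  h2 <- cohort$hap2[, idx, drop = FALSE]
  ok <- !rowSums(is.na(h1)) & !rowSums(is.na(h2))
  haps <- c(apply(h1[ok, , drop = FALSE], 1L, paste, collapse = ""),
            apply(h2[ok, , drop = FALSE], 1L, paste, collapse = ""))
  tab <- sort(table(haps), decreasing = TRUE)
  tibble(haplotype = names(tab), count = as.integer(tab))
}

#' Assemble a multi-InDel marker panel from screened loci
#'
#' Runs the formation pipeline on the loci that passed the FST screen:
#' greedy clustering by adjacent gap, haplotype enumeration in the cohort,
#' amplicon-size mapping, then filtering. A candidate cluster becomes a
#' marker iff (i) every adjacent gap is `< max_gap`, (ii) at least two
#' distinct haplotypes are observed, (iii) the largest observed amplicon is
#' strictly below `max_amplicon`, and (iv) no two observed haplotypes share
#' an amplicon size (CE genotyping must be invertible). The base amplicon
#' size is modeled as the marker's reference span plus `2 * flank_padding`,
#' standing in for primer placement.
#'
#' @param cohort A `phased_cohort`.
#' @param screen Screen-result tibble from [screen_loci()] (only rows with
#'   `pass` are used). Pass `NULL` to build from all cohort loci.
#' @param max_gap Strict adjacent-gap bound in bp.
#' @param max_amplicon Strict upper bound (bp) on observed amplicon sizes.
#' @param flank_padding Primer flank model parameter (bp added on each side).
#' @return An `indel_panel` (possibly zero markers). Rejected candidate
#'   clusters and their reasons are attached as attribute `"rejected"`; the
#'   observed haplotype tallies of kept markers as attribute `"observed"`.
#' @export
build_panel <- function(cohort, screen, max_gap = 250, max_amplicon = 300,
                        flank_padding = 30) {
  loci <- cohort$loci
  if (!is.null(screen)) {
    keep_ids <- screen$rsid[screen$pass]
    loci <- loci[loci$rsid %in% keep_ids, , drop = FALSE]
  }
  cand <- cluster_candidates(loci, max_gap = max_gap)
  if (nrow(cand) == 0L) return(empty_panel())

  kept <- list()
  observed <- list()
  rejected <- tibble(candidate_id = integer(), chrom = character(),
                     start = integer(), reason = character())
  for (cid in unique(cand$candidate_id)) {
    m <- cand[cand$candidate_id == cid, , drop = FALSE]
    haps <- enumerate_haplotypes(cohort, m)
    base <- (max(m$pos) - min(m$pos) + 1) + 2 * flank_padding
    smap <- compute_size_map(m, base)
    obs_sizes <- smap$size[smap$haplotype %in% haps$haplotype]
    reason <- NULL
    if (nrow(haps) < 2L) {
      reason <- sprintf("only %d haplotype observed", nrow(haps))
    } else if (max(obs_sizes) >= max_amplicon) {
      reason <- sprintf("max observed amplicon %g >= %g",
                        max(obs_sizes), max_amplicon)
    } else if (nrow(check_size_degeneracy(smap, haps$haplotype)) > 0L) {
      reason <- "amplicon-size collision among observed haplotypes"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- mutate(m, base_size = base)
      observed[[length(observed) + 1L]] <- haps
    } else {
      rejected <- bind_rows(rejected, tibble(
        candidate_id = cid, chrom = m$chrom[1], start = min(m$pos),
        reason = reason))
    }
  }
  if (!length(kept)) {
    out <- empty_panel()
    attr(out, "rejected") <- rejected
    return(out)
  }
  marker_ids <- sprintf("M%02d", seq_along(kept))
  loci_tab <- bind_rows(lapply(seq_along(kept), function(i) {
    mutate(kept[[i]], marker_id = marker_ids[i])
  }))
  base_sizes <- setNames(
    vapply(kept, function(m) m$base_size[1], numeric(1)), marker_ids)
  panel <- new_indel_panel(
    loci_tab[c("marker_id", "rsid", "chrom", "pos", "short_allele",
               "long_allele", "delta")],
    base_sizes = base_sizes, max_gap = max_gap,
    provenance = "built by build_panel()")
  names(observed) <- marker_ids
  attr(panel, "rejected") <- rejected
  attr(panel, "observed") <- observed
  panel
}

#' Build a panel directly from a cohort's planted clusters
#'
#' Validation cohorts produced by the simulators carry a `cluster_id`
#' column marking which loci were laid out as one tight cluster. This
#' helper turns every such cluster into a marker without applying the
#' discovery filters — the situation of a fixed, already-designed panel
#' being genotyped in new target cohorts.
#'
#' @param cohort A `phased_cohort` whose `loci` table has `cluster_id`.
#' @param flank_padding Primer flank model (bp each side) for base sizes.
#' @return An `indel_panel`.
#' @export
panel_from_clusters <- function(cohort, flank_padding = 30) {
  loci <- cohort$loci
  if (!"cluster_id" %in% names(loci) || all(is.na(loci$cluster_id))) {
    abort("cohort loci carry no cluster ids.")
  }
  loci <- loci[!is.na(loci$cluster_id), , drop = FALSE]
  ids <- unique(loci$cluster_id)
  marker_ids <- sprintf("M%02d", match(loci$cluster_id, ids))
  tab <- mutate(loci, marker_id = marker_ids)
  spans <- tab %>%
    group_by(.data$marker_id) %>%
    summarise(base = max(.data$pos) - min(.data$pos) + 1 + 2 * flank_padding,
              .groups = "drop")
  new_indel_panel(
    tab[c("marker_id", "rsid", "chrom", "pos", "short_allele",
          "long_allele", "delta")],
    base_sizes = setNames(spans$base, spans$marker_id),
    max_gap = Inf,
    provenance = "planted clusters")
}

empty_panel <- function() {
  out <- tibble(
    marker_id = character(), chrom = character(), start = integer(),
    end = integer(), n_loci = integer(), base_size = numeric(),
    loci = list(), size_map = list())
  class(out) <- c("indel_panel", class(out))
  out
}

#' Write a panel's genomic intervals as BED
#'
#' One 0-based half-open interval per marker, spanning the first to last
#' member locus.
#'
#' @param panel An `indel_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", panel$chrom, panel$start - 1L,
                   panel$end, panel$marker_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write haplotype-to-amplicon-size maps as JSON
#'
#' @param panel An `indel_panel` with computed size maps.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_maps_json <- function(panel, path) {
  maps <- lapply(panel$size_map, function(sm) {
    if (is.null(sm)) return(NULL)
    setNames(as.list(sm$size), sm$haplotype)
  })
  names(maps) <- panel$marker_id
  jsonlite::write_json(maps, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
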