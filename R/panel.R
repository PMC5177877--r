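#' Construct a multi-InDel panel
#'
#' A panel is a set of multi-InDel markers: ordered clusters of di-allelic
#' InDels treated as one multi-allelic locus whose alleles are haplotypes,
#' each haplotype observable on capillary electrophoresis as a distinct
#' amplicon size. The panel is stored as a nested tibble, one row per marker,
#' with member loci and the haplotype-to-size map as list-columns.
#'
#' @param loci Tibble with one row per member InDel: `marker_id`, `rsid`,
#'   `chrom`, `pos`, `short_allele`, `long_allele`, `delta`.
#' @param base_sizes Optional named numeric vector (names = marker ids):
#'   amplicon size in bp of the all-short haplotype. Markers with a known
#'   base size get a full haplotype-to-size map.
#' @param max_gap Maximum allowed gap (bp) between adjacent member loci.
#' @param provenance Free-text metadata carried as an attribute.
#' @return A tibble of class `indel_panel` with columns `marker_id`,
#'   `chrom`, `start`, `end`, `n_loci`, `base_size`, `loci` (list),
#'   `size_map` (list).
#' @export
new_indel_panel <- function(loci, base_sizes = NULL, max_gap = 250,
                            provenance = character()) {
  loci <- as_tibble(loci)
  need <- c("marker_id", "rsid", "chrom", "pos", "short_allele",
            "long_allele", "delta")
  if (!all(need %in% names(loci))) {
    abort(paste("panel loci need columns", paste(need, collapse = ", "), "."))
  }
  loci$marker_id <- as.character(loci$marker_id)
  if (anyDuplicated(loci$rsid)) {
    abort("a locus cannot belong to two markers (duplicate rsid).")
  }
  split_loci <- split(loci, factor(loci$marker_id, unique(loci$marker_id)))
  rows <- lapply(split_loci, function(m) {
    if (nrow(m) < 2L) {
      abort(sprintf("marker %s has %d locus; a multi-InDel needs at least 2.",
                    m$marker_id[1], nrow(m)))
    }
    if (length(unique(m$chrom)) != 1L) {
      abort(sprintf("marker %s spans multiple chromosomes.", m$marker_id[1]))
    }
    if (is.unsorted(m$pos, strictly = TRUE)) {
      abort(sprintf("marker %s member positions are not strictly increasing.",
                    m$marker_id[1]))
    }
    gaps <- diff(m$pos)
    if (any(gaps >= max_gap)) {
      abort(sprintf("marker %s has an adjacent gap of %d bp (>= %d).",
                    m$marker_id[1], max(gaps), max_gap))
    }
    bs <- if (!is.null(base_sizes) && m$marker_id[1] %in% names(base_sizes)) {
      as.numeric(base_sizes[[m$marker_id[1]]])
    } else {
      NA_real_
    }
    tibble(
      marker_id = m$marker_id[1],
      chrom = m$chrom[1],
      start = min(m$pos),
      end = max(m$pos),
      n_loci = nrow(m),
      base_size = bs,
      loci = list(m),
      size_map = list(if (is.na(bs)) NULL else compute_size_map(m, bs))
    )
  })
  out <- bind_rows(rows)
  attr(out, "provenance") <- provenance
  class(out) <- c("indel_panel", class(out))
  out
}

#' Amplicon-size map of a multi-InDel marker
#'
#' Enumerates all `2^k` allele-state haplotypes of a `k`-InDel marker and
#' assigns each its CE amplicon size: the all-short haplotype maps to
#' `base_size`, and every long allele carried adds that locus's length
#' difference.
#'
#' @param marker_loci Tibble of the marker's member loci (needs `delta`).
#' @param base_size Amplicon size (bp) of the all-short haplotype; > 0.
#' @return Tibble with columns `haplotype` (allele-state string such as
#'   `"01"`) and `size` (bp).
#' @examples
#' loci <- tibble::tibble(delta = c(1L, 4L))
#' compute_size_map(loci, base_size = 122)
#' @export
compute_size_map <- function(marker_loci, base_size) {
  if (base_size <= 0) abort("`base_size` must be positive.")
  k <- nrow(marker_loci)
  states <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  tibble(
    haplotype = apply(states, 1L, paste, collapse = ""),
    size = base_size + as.vector(states %*% marker_loci$delta)
  ) %>% arrange(.data$haplotype)
}

#' Detect amplicon-size collisions in a marker
#'
#' CE genotyping reads a haplotype off its amplicon size, which is only
#' well-defined if the size map is injective over the haplotypes that can
#' occur. Returns every pair of distinct haplotypes sharing a size.
#'
#' @param size_map Tibble from [compute_size_map()].
#' @param observed Optional character vector restricting the check to
#'   haplotypes actually observed in a cohort.
#' @return Tibble with columns `haplotype_a`, `haplotype_b`, `size`; zero
#'   rows when the (restricted) map is injective.
#' @export
check_size_degeneracy <- function(size_map, observed = NULL) {
  sm <- size_map
  if (!is.null(observed)) sm <- sm[sm$haplotype %in% observed, , drop = FALSE]
  out <- tibble(haplotype_a = character(), haplotype_b = character(),
                size = numeric())
  for (s in unique(sm$size[duplicated(sm$size)])) {
    haps <- sm$haplotype[sm$size == s]
    pairs <- utils::combn(haps, 2L)
    out <- bind_rows(out, tibble(haplotype_a = pairs[1L, ],
                                 haplotype_b = pairs[2L, ], size = s))
  }
  out
}

#' @export
print.indel_panel <- function(x, ...) {
  cat(sprintf("<indel_panel> %d markers, %d InDel loci\n",
              nrow(x), sum(x$n_loci)))
  NextMethod()
}

#' Read a panel-definition table
#'
#' Parses a TSV/CSV with columns `marker_id`, `rsid`, `chrom`, `pos`,
#' `alleles`, where `alleles` is a slash-separated pair such as `"AGAA/-"`
#' (`"-"` denotes the absent allele). Rows are grouped into markers by
#' `marker_id`; the shorter side of each pair becomes the short allele.
#'
#' @param path File path.
#' @param base_sizes Optional named base-size vector passed to
#'   [new_indel_panel()].
#' @return An `indel_panel`.
#' @export
read_panel_table <- function(path, base_sizes = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("marker_id", "rsid", "chrom", "pos", "alleles")
  if (!all(need %in% names(raw))) {
    abort(paste("panel table needs columns", paste(need, collapse = ", "), "."))
  }
  parts <- strsplit(raw$alleles, "/", fixed = TRUE)
  bad <- which(lengths(parts) != 2L | vapply(parts, function(p) any(p == ""), TRUE))
  if (length(bad)) {
    abort(sprintf("unparseable allele pair in row %d (rsid %s): %s",
                  bad[1], raw$rsid[bad[1]], raw$alleles[bad[1]]))
  }
  len <- function(a) ifelse(a == "-", 0L, nchar(a))
  a1 <- vapply(parts, `[`, character(1), 1L)
  a2 <- vapply(parts, `[`, character(1), 2L)
  eqlen <- which(len(a1) == len(a2))
  if (length(eqlen)) {
    abort(sprintf("row %d (rsid %s): alleles have equal length, not an InDel.",
                  eqlen[1], raw$rsid[eqlen[1]]))
  }
  short <- ifelse(len(a1) < len(a2), a1, a2)
  long <- ifelse(len(a1) < len(a2), a2, a1)
  loci <- tibble(
    marker_id = raw$marker_id,
    rsid = raw$rsid,
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    short_allele = short,
    long_allele = long,
    delta = len(long) - len(short)
  )
  new_indel_panel(loci, base_sizes = base_sizes,
                  provenance = paste("read from", path))
}

#' Read an amplicon-size table
#'
#' Reads a TSV with at least `marker_id` and `amplicon_size` columns (bp per
#' marker in the multiplex), suitable for supplying measured base sizes.
#'
#' @param path File path.
#' @return Tibble with `marker_id` (character) and `amplicon_size` (numeric).
#' @export
read_amplicon_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("marker_id", "amplicon_size") %in% names(raw))) {
    abort("amplicon table needs columns `marker_id` and `amplicon_size`.")
  }
  raw$marker_id <- as.character(raw$marker_id)
  raw$amplicon_size <- as.numeric(raw$amplicon_size)
  raw
}

#' Write a panel back to the tabular definition format
#'
#' Inverse of [read_panel_table()]: one row per member InDel with the
#' slash-separated allele pair (short first).
#'
#' @param panel An `indel_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(panel, path) {
  loci <- panel_loci(panel)
  out <- tibble(
    marker_id = loci$marker_id,
    rsid = loci$rsid,
    chrom = loci$chrom,
    pos = loci$pos,
    alleles = paste0(loci$short_allele, "/", loci$long_allele)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Flatten a panel to its member-locus table
#'
#' @param panel An `indel_panel`.
#' @return Tibble of all member loci with their `marker_id`.
#' @export
panel_loci <- function(panel) {
  bind_rows(panel$loci)
}
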