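#' Haplotype-frequency tables on disk
#'
#' Frequency tables are stored as one CSV per marker in a directory, in the
#' layout classifiers such as Snipper consume: populations as rows,
#' haplotype keys as columns, relative frequencies in the cells. The
#' package additionally writes an `n_chrom` column (chromosomes counted per
#' population), which the classifier needs to reconstruct counts for
#' pseudocount smoothing; it is optional on read.
#'
#' `write_frequency_tables()` and `read_frequency_tables()` are exact
#' inverses, including haplotype columns whose frequency is zero in every
#' population.
#'
#' @param freqs Tibble with columns `marker_id`, `population`, `haplotype`,
#'   `frequency` and optionally `n_chrom`.
#' @param dir Directory holding one `marker_<id>.csv` per marker.
#' @param tol Row-sum tolerance on read; a population row whose frequencies
#'   do not sum to 1 within `tol` is a hard error naming the marker and
#'   population.
#' @return `write_frequency_tables()` returns `dir` invisibly;
#'   `read_frequency_tables()` returns the long-format tibble.
#' @name frequency_tables
NULL

#' @rdname frequency_tables
#' @export
write_frequency_tables <- function(freqs, dir) {
  validate_frequency_table(freqs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  has_n <- "n_chrom" %in% names(freqs)
  for (mid in unique(freqs$marker_id)) {
    m <- freqs[freqs$marker_id == mid, , drop = FALSE]
    wide <- m %>%
      select("population", if (has_n) "n_chrom" else NULL,
             "haplotype", "frequency") %>%
      tidyr::pivot_wider(names_from = "haplotype",
                         values_from = "frequency", values_fill = 0)
    readr::write_csv(wide, file.path(dir, paste0("marker_", mid, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname frequency_tables
#' @export
read_frequency_tables <- function(dir, tol = 1e-9) {
  files <- sort(list.files(dir, pattern = "^marker_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) abort(sprintf("no marker_*.csv files in %s.", dir))
  out <- lapply(files, function(f) {
    mid <- sub("^marker_(.*)\\.csv$", "\\1", basename(f))
    wide <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (!"population" %in% names(wide)) {
      abort(sprintf("%s: first column must be `population`.", basename(f)))
    }
    hap_cols <- setdiff(names(wide), c("population", "n_chrom"))
    sums <- rowSums(wide[hap_cols])
    bad <- which(abs(sums - 1) > tol)
    if (length(bad)) {
      abort(sprintf(
        "marker %s, population %s: frequencies sum to %.12g, not 1.",
        mid, wide$population[bad[1]], sums[bad[1]]))
    }
    long <- tidyr::pivot_longer(wide, dplyr::all_of(hap_cols),
                                names_to = "haplotype",
                                values_to = "frequency")
    long$marker_id <- mid
    long$haplotype <- as.character(long$haplotype)
    cols <- c("marker_id", "population", "haplotype", "frequency")
    if ("n_chrom" %in% names(long)) cols <- c(cols, "n_chrom")
    long[cols]
  })
  bind_rows(out)
}

validate_frequency_table <- function(freqs, tol = 1e-9) {
  need <- c("marker_id", "population", "haplotype", "frequency")
  if (!all(need %in% names(freqs))) {
    abort(paste("frequency table needs columns",
                paste(need, collapse = ", "), "."))
  }
  if (any(freqs$frequency < -tol | freqs$frequency > 1 + tol)) {
    abort("frequencies must lie in [0, 1].")
  }
  sums <- freqs %>%
    group_by(.data$marker_id, .data$population) %>%
    summarise(s = sum(.data$frequency), .groups = "drop")
  bad <- which(abs(sums$s - 1) > tol)
  if (length(bad)) {
    abort(sprintf("marker %s, population %s: frequencies sum to %.12g, not 1.",
                  sums$marker_id[bad[1]], sums$population[bad[1]],
                  sums$s[bad[1]]))
  }
  invisible(freqs)
}
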