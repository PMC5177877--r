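#' Principal component analysis of multi-allelic marker genotypes
#'
#' Encodes each marker as haplotype-dosage columns (how many copies of each
#' haplotype a sample carries: 0, 1 or 2), drops one reference column per
#' marker to remove the exact within-marker collinearity (dosages sum to
#' 2), centres the columns and eigendecomposes the covariance matrix.
#'
#' @param genotypes Tibble of marker genotypes (`sample_id`, `marker_id`,
#'   `hap1`, `hap2`, optionally `population` which is carried into the
#'   scores).
#' @return An object of class `aim_pca`: `scores` (tibble of sample
#'   coordinates), `explained` (variance fractions summing to 1),
#'   `rotation`, `center`.
#' @export
pca_genotypes <- function(genotypes) {
  samples <- unique(genotypes$sample_id)
  if (length(samples) < 2L) abort("PCA needs at least 2 samples.")
  markers <- unique(genotypes$marker_id)
  cols <- list()
  for (mid in markers) {
    g <- genotypes[genotypes$marker_id == mid, , drop = FALSE]
    haps <- sort(unique(c(g$hap1, g$hap2)))
    dose <- matrix(0, length(samples), length(haps),
                   dimnames = list(samples, paste(mid, haps, sep = ":")))
    i <- match(g$sample_id, samples)
    dose[cbind(i, match(g$hap1, haps))] <-
      dose[cbind(i, match(g$hap1, haps))] + 1
    dose[cbind(i, match(g$hap2, haps))] <-
      dose[cbind(i, match(g$hap2, haps))] + 1
    missing_rows <- setdiff(seq_along(samples), i)
    if (length(missing_rows)) dose[missing_rows, ] <- NA
    cols[[mid]] <- dose[, -1L, drop = FALSE]  # drop reference haplotype
  }
  X <- do.call(cbind, cols)
  # mean-impute the (rare) samples missing a marker so they stay plottable
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  total_var <- sum(apply(Xc, 2L, var))
  if (total_var == 0) {
    npc <- max(1L, min(nrow(X) - 1L, ncol(X)))
    scores <- matrix(0, nrow(X), npc,
                     dimnames = list(samples, paste0("PC", seq_len(npc))))
    explained <- rep(0, npc)
    rotation <- matrix(0, ncol(X), npc)
  } else {
    fit <- prcomp(Xc, center = FALSE, scale. = FALSE)
    scores <- fit$x
    explained <- fit$sdev^2 / sum(fit$sdev^2)
    rotation <- fit$rotation
  }
  score_tbl <- as_tibble(scores)
  score_tbl$sample_id <- samples
  if ("population" %in% names(genotypes)) {
    lab <- genotypes %>% distinct(.data$sample_id, .data$population)
    score_tbl <- left_join(score_tbl, lab, by = "sample_id")
  }
  score_tbl <- select(score_tbl, "sample_id",
                      dplyr::any_of("population"), dplyr::everything())
  structure(
    list(scores = score_tbl, explained = explained,
         rotation = rotation, center = ctr),
    class = "aim_pca")
}

#' @method print aim_pca
#' @export
print.aim_pca <- function(x, ...) {
  cat(sprintf("<aim_pca> %d samples, %d components; PC1 explains %.1f%%\n",
              nrow(x$scores), length(x$explained), 100 * x$explained[1]))
  invisible(x)
}

#' @method tidy aim_pca
#' @export
tidy.aim_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @method glance aim_pca
#' @export
glance.aim_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_components = length(x$explained),
         pve_pc1 = x$explained[1],
         pve_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Two-dimensional PCA scatter plot
#'
#' @param object An `aim_pca`.
#' @param dims Two components to display.
#' @param ... Unused.
#' @return A ggplot object, coloured by population when labels are present.
#' @method autoplot aim_pca
#' @export
autoplot.aim_pca <- function(object, dims = c(1L, 2L), ...) {
  d <- object$scores
  xy <- paste0("PC", dims)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xy[1]]], .data[[xy[2]]]))
  if ("population" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xy[1], 100 * object$explained[dims[1]]),
    y = sprintf("%s (%.1f%%)", xy[2], 100 * object$explained[dims[2]])) +
    ggplot2::theme_minimal()
}
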