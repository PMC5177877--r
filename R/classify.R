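#' Build a naive-Bayes training set from haplotype counts
#'
#' Packages per-marker, per-population haplotype counts as the classifier's
#' training set, with Laplace-style pseudocount smoothing: the smoothed
#' frequency of haplotype `h` is `(c_h + alpha) / (n_chrom + alpha * H)`
#' where `c_h` is its chromosome count, `n_chrom` the chromosomes counted
#' for that marker and population, and `H` the number of haplotype classes
#' the marker has in training. `alpha = 0` reproduces raw counting.
#'
#' @param freqs Tibble from [count_haplotype_frequencies()] (needs `count`
#'   and `n_chrom`), or a frequency-only table (`frequency` and `n_chrom`),
#'   e.g. from [read_frequency_tables()].
#' @param alpha Pseudocount per haplotype class (default 1).
#' @param n_chrom Fallback chromosome count used when `freqs` carries
#'   neither `count` nor `n_chrom`.
#' @return An object of class `aim_training`.
#' @export
build_training_set <- function(freqs, alpha = 1, n_chrom = NULL) {
  f <- as_tibble(freqs)
  if (!"n_chrom" %in% names(f)) {
    if (is.null(n_chrom)) {
      abort("`freqs` lacks `n_chrom`; supply the chromosome count explicitly.")
    }
    f$n_chrom <- n_chrom
  }
  if (!"count" %in% names(f)) {
    if (!"frequency" %in% names(f)) {
      abort("`freqs` needs a `count` or `frequency` column.")
    }
    f$count <- f$frequency * f$n_chrom
  }
  if (alpha < 0) abort("`alpha` must be non-negative.")
  pops_by_marker <- f %>%
    group_by(.data$marker_id) %>%
    summarise(pops = list(sort(unique(.data$population))), .groups = "drop")
  ref <- pops_by_marker$pops[[1]]
  same <- vapply(pops_by_marker$pops, identical, logical(1), y = ref)
  if (!all(same)) {
    abort("every marker must be trained on the same population set.")
  }
  H <- f %>% group_by(.data$marker_id) %>%
    summarise(H = dplyr::n_distinct(.data$haplotype), .groups = "drop")
  structure(
    list(counts = f %>% select("marker_id", "population", "haplotype",
                               "count", "n_chrom"),
         H = setNames(H$H, H$marker_id),
         populations = ref,
         markers = names(setNames(H$H, H$marker_id)),
         alpha = alpha),
    class = "aim_training")
}

# Smoothed log-frequency lookup for one population: a named vector keyed
# "marker\rhaplotype", plus the per-marker floor for unseen haplotypes.
training_lookup <- function(training, population) {
  f <- training$counts[training$counts$population == population, , drop = FALSE]
  a <- training$alpha
  denom <- f$n_chrom + a * unname(training$H[f$marker_id])
  p <- (f$count + a) / denom
  nper <- f %>% distinct(.data$marker_id, .data$n_chrom)
  floor_p <- a / (nper$n_chrom + a * unname(training$H[nper$marker_id]))
  list(
    p = setNames(p, paste(f$marker_id, f$haplotype, sep = "\r")),
    floor = setNames(floor_p, nper$marker_id)
  )
}

# Log-likelihood matrix (samples x populations) under per-population HWE.
ll_matrix <- function(genotypes, training) {
  g <- genotypes[genotypes$marker_id %in% training$markers, , drop = FALSE]
  if (nrow(g) == 0L) {
    abort("no marker shared between the sample genotypes and the training set.")
  }
  sample_ids <- unique(genotypes$sample_id)
  out <- matrix(NA_real_, length(sample_ids), length(training$populations),
                dimnames = list(sample_ids, training$populations))
  hom <- g$hap1 == g$hap2
  k1 <- paste(g$marker_id, g$hap1, sep = "\r")
  k2 <- paste(g$marker_id, g$hap2, sep = "\r")
  for (pop in training$populations) {
    lut <- training_lookup(training, pop)
    p1 <- lut$p[k1]
    p2 <- lut$p[k2]
    p1[is.na(p1)] <- lut$floor[g$marker_id[is.na(p1)]]
    p2[is.na(p2)] <- lut$floor[g$marker_id[is.na(p2)]]
    logP <- ifelse(hom, 2 * log(p1), log(2) + log(p1) + log(p2))
    out[, pop] <- vapply(sample_ids, function(s)
      sum(logP[g$sample_id == s]), numeric(1))
  }
  out
}

#' Log-likelihood of one sample's genotypes under a population
#'
#' Naive-Bayes likelihood with Hardy-Weinberg within the population and
#' independence across markers: a homozygote `(i, i)` contributes
#' `p_i^2`, a heterozygote `(i, j)` contributes `2 p_i p_j`, with smoothed
#' training frequencies (see [build_training_set()]). Markers missing from
#' the sample are skipped.
#'
#' @param genotypes Tibble of one sample's marker genotypes (`sample_id`,
#'   `marker_id`, `hap1`, `hap2`).
#' @param training An `aim_training` object.
#' @param population One of the training populations.
#' @return The log-likelihood (natural log).
#' @export
genotype_log_likelihood <- function(genotypes, training, population) {
  if (length(unique(genotypes$sample_id)) != 1L) {
    abort("`genotypes` must contain exactly one sample.")
  }
  if (!population %in% training$populations) {
    abort(sprintf("population %s not in training set.", population))
  }
  ll_matrix(genotypes, training)[1L, population]
}

#' Snipper-style ancestry assignment
#'
#' Assigns each sample to the reference population with the highest
#' naive-Bayes likelihood, reporting the ratio of the two highest
#' likelihoods as the assignment's strength, together with posterior
#' probabilities under a uniform prior over populations. An exact tie of
#' the top two likelihoods (within `1e-12` in log space) yields status
#' `"tie"` with no forced assignment.
#'
#' @param genotypes Tibble of marker genotypes for any number of samples.
#' @param training An `aim_training` object.
#' @return Tibble with one row per sample: `sample_id`, `best_pop`,
#'   `second_pop`, `loglik_best`, `loglik_second`, `lr`, `log10_lr`,
#'   `posterior_best`, `status`. The full log-likelihood matrix is attached
#'   as attribute `"loglik"`.
#' @export
classify_samples <- function(genotypes, training) {
  ll <- ll_matrix(genotypes, training)
  ord <- t(apply(ll, 1L, order, decreasing = TRUE))
  best <- colnames(ll)[ord[, 1L]]
  second <- colnames(ll)[ord[, 2L]]
  l1 <- ll[cbind(seq_len(nrow(ll)), ord[, 1L])]
  l2 <- ll[cbind(seq_len(nrow(ll)), ord[, 2L])]
  post <- t(apply(ll, 1L, function(x) {
    w <- exp(x - max(x))
    w / sum(w)
  }))
  tie <- (l1 - l2) < 1e-12
  out <- tibble(
    sample_id = rownames(ll),
    best_pop = ifelse(tie, NA_character_, best),
    second_pop = second,
    loglik_best = l1,
    loglik_second = l2,
    lr = exp(l1 - l2),
    log10_lr = (l1 - l2) / log(10),
    posterior_best = post[cbind(seq_len(nrow(ll)), ord[, 1L])],
    status = ifelse(tie, "tie", "assigned")
  )
  attr(out, "loglik") <- ll
  out
}

#' Blind-trial evaluation of the ancestry classifier
#'
#' Holds out `n_holdout` samples drawn uniformly (without replacement) from
#' the pooled labeled cohort, recounts training haplotype frequencies from
#' the remaining samples only, classifies the holdouts, and reports the
#' fraction whose assignment matches their recorded population.
#'
#' @param genotypes Labeled marker genotypes (`sample_id`, `population`,
#'   `marker_id`, `hap1`, `hap2`).
#' @param n_holdout Number of blind samples (default 10).
#' @param seed Integer seed for the holdout draw.
#' @param alpha Pseudocount for [build_training_set()].
#' @return List with `accuracy`, `results` (per-holdout classification with
#'   a `truth` column), and `holdout_ids`.
#' @export
blind_trial <- function(genotypes, n_holdout = 10, seed = NULL, alpha = 1) {
  ids <- unique(genotypes$sample_id)
  if (n_holdout >= length(ids)) {
    abort("`n_holdout` must be smaller than the number of samples.")
  }
  if (!is.null(seed)) set.seed(seed)
  hold <- sample(ids, n_holdout)
  train_g <- genotypes[!genotypes$sample_id %in% hold, , drop = FALSE]
  test_g <- genotypes[genotypes$sample_id %in% hold, , drop = FALSE]
  left <- unique(train_g$population)
  gone <- setdiff(unique(genotypes$population), left)
  if (length(gone)) {
    abort(paste("population(s) with no training sample after holdout:",
                paste(gone, collapse = ", ")))
  }
  training <- build_training_set(count_haplotype_frequencies(train_g),
                                 alpha = alpha)
  res <- classify_samples(test_g, training)
  truth <- test_g %>% distinct(.data$sample_id, .data$population)
  res <- left_join(res, rename(truth, truth = "population"), by = "sample_id")
  res$correct <- !is.na(res$best_pop) & res$best_pop == res$truth
  list(accuracy = mean(res$correct), results = res, holdout_ids = hold)
}
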