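#' No-admixture model-based clustering of marker genotypes
#'
#' Gibbs sampler for the no-admixture clustering model: each individual
#' originates wholly from one of `K` clusters; each cluster has its own
#' haplotype frequencies per marker, with independent (uncorrelated)
#' symmetric Dirichlet(`lambda`) priors; genotype probabilities follow
#' Hardy-Weinberg within a cluster. The sampler alternates frequency and
#' assignment updates and records the data log-likelihood at each kept
#' iteration. Assignment posteriors are empirical label frequencies over
#' kept iterations, after per-iteration greedy label alignment to the first
#' kept iteration (label switching). `ln P(X|K)` is estimated from the
#' trace as mean minus half variance; at `K = 1` the marginal likelihood
#' has a closed Dirichlet-multinomial form, which is returned exactly
#' instead of the trace estimate.
#'
#' @param genotypes Tibble of marker genotypes (`sample_id`, `marker_id`,
#'   `hap1`, `hap2`; any consistent haplotype key namespace).
#' @param K Number of clusters (`1 <= K <=` number of samples).
#' @param lambda Dirichlet concentration for haplotype frequencies.
#' @param burn_in,kept Discarded and recorded iteration counts.
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `structure_fit`: fields `K`, `posterior`
#'   (samples x K matrix, rows sum to 1), `assignment` (modal cluster),
#'   `trace`, `lnP` (exact at K = 1, trace estimate otherwise),
#'   `lnP_trace` (the trace estimate at every K; the scale on which
#'   different K are compared), `seed`, `burn_in`, `kept`, `sample_ids`.
#' @export
gibbs_no_admixture <- function(genotypes, K, lambda = 1,
                               burn_in = 5000, kept = 5000, seed = NULL) {
  enc <- encode_genotypes(genotypes)
  if (K > length(enc$sample_ids)) abort("K exceeds the number of samples.")
  if (kept < 2L) abort("need at least 2 kept iterations.")
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_no_admixture_cpp(enc$a1, enc$a2, enc$nhap, as.integer(K),
                                lambda, as.integer(burn_in), as.integer(kept))
  lnP_trace <- estimate_lnP(res$trace)
  # at K = 1 the marginal likelihood has an exact Dirichlet-multinomial
  # form; report it as the headline lnP (the trace estimate stays available
  # as lnP_trace, the quantity comparable across K in a scan)
  lnP <- if (K == 1L) lnP_K1_closed_form(enc, lambda) else lnP_trace
  rownames(res$posterior) <- enc$sample_ids
  structure(
    list(K = as.integer(K), posterior = res$posterior,
         assignment = max.col(res$posterior, ties.method = "first"),
         trace = as.numeric(res$trace), lnP = lnP, lnP_trace = lnP_trace,
         seed = seed, burn_in = burn_in, kept = kept,
         lambda = lambda, sample_ids = enc$sample_ids),
    class = "structure_fit")
}

# Integer-code genotypes for the C++ sampler: per marker a 0-based haplotype
# alphabet; -1 marks a sample missing that marker.
encode_genotypes <- function(genotypes) {
  need <- c("sample_id", "marker_id", "hap1", "hap2")
  if (!all(need %in% names(genotypes))) {
    abort(paste("genotypes need columns", paste(need, collapse = ", "), "."))
  }
  sample_ids <- unique(genotypes$sample_id)
  markers <- unique(genotypes$marker_id)
  n <- length(sample_ids)
  m <- length(markers)
  a1 <- matrix(-1L, n, m)
  a2 <- matrix(-1L, n, m)
  nhap <- integer(m)
  alphabets <- vector("list", m)
  for (j in seq_len(m)) {
    g <- genotypes[genotypes$marker_id == markers[j], , drop = FALSE]
    alpha <- sort(unique(c(g$hap1, g$hap2)))
    alphabets[[j]] <- alpha
    nhap[j] <- length(alpha)
    i <- match(g$sample_id, sample_ids)
    a1[i, j] <- match(g$hap1, alpha) - 1L
    a2[i, j] <- match(g$hap2, alpha) - 1L
  }
  list(a1 = a1, a2 = a2, nhap = nhap, sample_ids = sample_ids,
       markers = markers, alphabets = alphabets)
}

# Exact log marginal likelihood at K = 1: with all samples in one cluster,
# integrating the Dirichlet prior over each marker's frequencies gives a
# Dirichlet-multinomial, times 2 per heterozygote for the unordered pair.
lnP_K1_closed_form <- function(enc, lambda) {
  total <- 0
  for (j in seq_along(enc$nhap)) {
    h1 <- enc$a1[, j]
    h2 <- enc$a2[, j]
    ok <- h1 >= 0
    cnt <- tabulate(c(h1[ok], h2[ok]) + 1L, nbins = enc$nhap[j])
    H <- enc$nhap[j]
    total <- total + sum(h1[ok] != h2[ok]) * log(2) +
      lgamma(H * lambda) - H * lgamma(lambda) +
      sum(lgamma(lambda + cnt)) - lgamma(H * lambda + sum(cnt))
  }
  total
}

#' Estimate ln P(X|K) from a log-likelihood trace
#'
#' The standard model-evidence approximation used with no-admixture runs:
#' the mean of the kept-iteration log-likelihoods minus half their sample
#' variance.
#'
#' @param trace Numeric vector of kept-iteration log-likelihoods
#'   (length >= 2).
#' @return A single number.
#' @examples
#' estimate_lnP(c(-100, -102))  # -101 - 2/2 = -102
#' @export
estimate_lnP <- function(trace) {
  if (length(trace) < 2L) abort("trace must have at least 2 values.")
  mean(trace) - var(trace) / 2
}

#' @method print structure_fit
#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf("<structure_fit> K = %d, %d samples, ln P(X|K) = %.2f\n",
              x$K, length(x$sample_ids), x$lnP))
  invisible(x)
}

#' Run replicated clustering across a range of K
#'
#' Fits the no-admixture sampler for each `K` in `k_range` with
#' `replicates` independent seeds, then selects the optimum `K` by the
#' Evanno delta-K procedure (see [evanno_delta_k()]).
#'
#' @inheritParams gibbs_no_admixture
#' @param k_range Integer vector of K values (e.g. `1:7`).
#' @param replicates Replicate runs per K.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return An object of class `structure_scan`: `runs` (tibble with `K`,
#'   `replicate`, `seed`, `lnP`, and the fit as a list-column) and
#'   `selection` (a `k_selection`).
#' @export
structure_scan <- function(genotypes, k_range = 1:7, replicates = 5,
                           lambda = 1, burn_in = 5000, kept = 5000,
                           seed = NULL) {
  if (is.null(seed)) abort("`seed` is required for a replicated scan.")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                             length(k_range) * replicates),
                  nrow = length(k_range))
  rows <- list()
  for (i in seq_along(k_range)) {
    for (r in seq_len(replicates)) {
      fit <- gibbs_no_admixture(genotypes, K = k_range[i], lambda = lambda,
                                burn_in = burn_in, kept = kept,
                                seed = seeds[i, r])
      rows[[length(rows) + 1L]] <- tibble(
        K = k_range[i], replicate = r, seed = seeds[i, r],
        lnP = fit$lnP_trace, fit = list(fit))
    }
  }
  runs <- bind_rows(rows)
  structure(
    list(runs = runs,
         selection = evanno_delta_k(runs[c("K", "lnP")])),
    class = "structure_scan")
}

#' Evanno delta-K selection of the optimum number of clusters
#'
#' Computes, per K, the mean and standard deviation of `ln P(X|K)` over
#' replicates and the delta-K statistic
#' `|L(K+1) - 2 L(K) + L(K-1)| / sd(K)` (defined for interior K with
#' nonzero replicate s.d.). The optimum is the interior K maximising
#' delta-K. Because delta-K cannot evaluate K = 1, the mean `ln P(X|K)`
#' profile is consulted first: delta-K is only applied when some K > 1
#' improves mean `ln P(X|K)` over the smallest K by more than replicate
#' noise (three times the largest replicate standard deviation);
#' otherwise there is no evidence of structure and the selection falls
#' back to the K with maximal mean `ln P(X|K)` — in the no-evidence case
#' the smallest K. The fallback is also used when fewer than three K
#' values are available or no interior delta-K is defined.
#'
#' @param lnp Tibble (or data frame) with columns `K` and `lnP`, one row
#'   per replicate run.
#' @return An object of class `k_selection`: `table` (per-K `mean_lnP`,
#'   `sd_lnP`, `delta_K`), `optimum_K`, `method` (`"delta_K"` or
#'   `"max_lnP"`) and `note`.
#' @export
evanno_delta_k <- function(lnp) {
  tab <- as_tibble(lnp) %>%
    group_by(K = .data$K) %>%
    summarise(mean_lnP = mean(.data$lnP),
              sd_lnP = if (n() > 1L) stats::sd(.data$lnP) else 0,
              n_rep = n(), .groups = "drop") %>%
    arrange(.data$K)
  ks <- tab$K
  dk <- rep(NA_real_, nrow(tab))
  if (nrow(tab) >= 3L) {
    for (i in 2:(nrow(tab) - 1L)) {
      contiguous <- ks[i - 1L] == ks[i] - 1L && ks[i + 1L] == ks[i] + 1L
      if (contiguous && tab$sd_lnP[i] > 0) {
        dk[i] <- abs(tab$mean_lnP[i + 1L] - 2 * tab$mean_lnP[i] +
                       tab$mean_lnP[i - 1L]) / tab$sd_lnP[i]
      }
    }
  }
  tab$delta_K <- dk
  note <- NA_character_
  # evidence of structure: lnP gain over the smallest K beyond replicate noise
  margin <- max(tab$mean_lnP) - tab$mean_lnP[which.min(ks)]
  noise <- max(tab$sd_lnP)
  no_structure <- margin <= 3 * noise
  if (all(is.na(dk))) {
    method <- "max_lnP"
    optimum <- ks[which.max(tab$mean_lnP)]
    note <- "delta-K undefined (need >= 3 consecutive K with replicate variance); using max mean lnP"
  } else if (no_structure) {
    method <- "max_lnP"
    optimum <- min(ks)
    note <- "lnP gain over the smallest K is within replicate noise; no support for additional clusters"
  } else {
    method <- "delta_K"
    optimum <- ks[which.max(replace(dk, is.na(dk), -Inf))]
  }
  structure(list(table = tab, optimum_K = optimum, method = method,
                 note = note),
            class = "k_selection")
}

#' @method print k_selection
#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> optimum K = %d (%s)\n", x$optimum_K, x$method))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  print(x$table)
  invisible(x)
}

#' Align replicate clustering runs and average their posteriors
#'
#' Resolves label switching across replicate runs of the same K: each
#' run's cluster labels are permuted to maximise agreement with the first
#' run (exhaustively over the `K!` permutations, feasible for the K ranges
#' used here), then the aligned posteriors are averaged.
#'
#' @param runs List of `structure_fit` objects sharing `K` and samples.
#' @return List with `mean_posterior` (samples x K) and `aligned` (list of
#'   permuted posterior matrices).
#' @export
align_replicates <- function(runs) {
  if (!length(runs)) abort("no runs supplied.")
  K <- runs[[1]]$K
  ids <- runs[[1]]$sample_ids
  for (r in runs) {
    if (r$K != K) abort("runs disagree on K.")
    if (!identical(r$sample_ids, ids)) abort("runs disagree on the sample set.")
  }
  perms <- perm_matrix(K)
  ref <- runs[[1]]$posterior
  aligned <- lapply(runs, function(r) {
    best <- NULL
    best_score <- -Inf
    for (i in seq_len(nrow(perms))) {
      q <- r$posterior[, perms[i, ], drop = FALSE]
      score <- sum(q * ref)
      if (score > best_score) {
        best_score <- score
        best <- q
      }
    }
    colnames(best) <- colnames(ref)
    best
  })
  mean_post <- Reduce(`+`, aligned) / length(aligned)
  list(mean_posterior = mean_post, aligned = aligned)
}

perm_matrix <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(K - 1L)
  out <- matrix(0L, 0L, K)
  for (pos in seq_len(K)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                            sub[, seq(pos, K - 1L)[seq_len(K - pos)],
                                drop = FALSE]))
  }
  out
}

#' @method tidy structure_fit
#' @export
tidy.structure_fit <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, x$K),
    cluster = rep(seq_len(x$K), each = length(x$sample_ids)),
    posterior = as.vector(x$posterior)
  )
}

#' @method glance structure_fit
#' @export
glance.structure_fit <- function(x, ...) {
  tibble(K = x$K, lnP = x$lnP, n_samples = length(x$sample_ids),
         burn_in = x$burn_in, kept = x$kept, seed = x$seed %||% NA_integer_)
}

#' @method tidy structure_scan
#' @export
tidy.structure_scan <- function(x, ...) {
  select(x$runs, "K", "replicate", "seed", "lnP")
}

#' @method glance structure_scan
#' @export
glance.structure_scan <- function(x, ...) {
  tibble(optimum_K = x$selection$optimum_K, method = x$selection$method,
         n_runs = nrow(x$runs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Membership bar plot for a clustering fit
#'
#' The familiar stacked-bar display of per-sample assignment posteriors,
#' one bar per individual, optionally grouped by a known label.
#'
#' @param object A `structure_fit`.
#' @param labels Optional named vector (sample id -> group) used to order
#'   and facet the bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot structure_fit
#' @export
autoplot.structure_fit <- function(object, labels = NULL, ...) {
  d <- tidy(object)
  if (!is.null(labels)) {
    d$group <- labels[d$sample_id]
    d$sample_id <- factor(d$sample_id, names(sort(labels)))
  } else {
    d$sample_id <- factor(d$sample_id, object$sample_ids)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id,
                                       y = .data$posterior,
                                       fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership posterior", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(labels)) {
    p <- p + ggplot2::facet_grid(~group, scales = "free_x", space = "free_x")
  }
  p
}

#' Delta-K and mean lnP profile plot
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot object showing mean `ln P(X|K)` (with s.d. bars) and
#'   delta-K against K.
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  tab <- object$table
  long <- bind_rows(
    tibble(K = tab$K, value = tab$mean_lnP, panel = "mean ln P(X|K)"),
    tibble(K = tab$K, value = tab$delta_K, panel = "delta K")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::geom_vline(xintercept = object$optimum_K, linetype = 2) +
    ggplot2::theme_minimal()
}
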