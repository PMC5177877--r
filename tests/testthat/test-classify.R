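worked_training <- function(alpha = 0) {
  # two markers, two haplotypes each, frequencies as printed-style tables
  freqs <- tibble::tibble(
    marker_id = rep(c("m1", "m2"), each = 4),
    population = rep(c("pop1", "pop1", "pop2", "pop2"), 2),
    haplotype = rep(c("A", "B"), 4),
    frequency = c(0.7, 0.3, 0.2, 0.8, 0.9, 0.1, 0.4, 0.6),
    n_chrom = 10
  )
  build_training_set(freqs, alpha = alpha)
}

test_that("log-likelihoods match the hand arithmetic oracle", {
  tr <- worked_training(alpha = 0)
  g <- tibble::tibble(
    sample_id = "s", marker_id = c("m1", "m2"),
    hap1 = c("A", "A"), hap2 = c("B", "A"))
  ll1 <- log(2 * 0.7 * 0.3) + log(0.9^2)
  ll2 <- log(2 * 0.2 * 0.8) + log(0.4^2)
  expect_equal(genotype_log_likelihood(g, tr, "pop1"), ll1,
               tolerance = 1e-12)
  expect_equal(genotype_log_likelihood(g, tr, "pop2"), ll2,
               tolerance = 1e-12)
  res <- classify_samples(g, tr)
  expect_equal(res$best_pop, "pop1")
  expect_equal(res$lr, exp(ll1 - ll2), tolerance = 1e-12)
  expect_gte(res$lr, 1)
  expect_equal(res$status, "assigned")
})

test_that("identical frequencies across populations give symmetric ties", {
  freqs <- tibble::tibble(
    marker_id = "m1", population = rep(c("P1", "P2"), each = 2),
    haplotype = rep(c("A", "B"), 2), frequency = rep(c(0.6, 0.4), 2),
    n_chrom = 20)
  tr <- build_training_set(freqs, alpha = 1)
  g <- tibble::tibble(sample_id = "s", marker_id = "m1",
                      hap1 = "A", hap2 = "B")
  expect_equal(genotype_log_likelihood(g, tr, "P1"),
               genotype_log_likelihood(g, tr, "P2"))
  res <- classify_samples(g, tr)
  expect_equal(res$status, "tie")
  expect_true(is.na(res$best_pop))
})

test_that("a private haplotype drives assignment to its population", {
  freqs <- tibble::tibble(
    marker_id = "m1", population = rep(c("A", "B"), each = 2),
    haplotype = rep(c("x", "y"), 2), frequency = c(1, 0, 0, 1),
    n_chrom = 50)
  tr <- build_training_set(freqs, alpha = 1)
  g <- tibble::tibble(sample_id = "s", marker_id = "m1",
                      hap1 = "x", hap2 = "x")
  res <- classify_samples(g, tr)
  expect_equal(res$best_pop, "A")
  expect_gt(res$lr, 1)
})

test_that("uninformative markers and marker order leave ratios unchanged", {
  tr <- worked_training(alpha = 0)
  g <- tibble::tibble(
    sample_id = "s", marker_id = c("m1", "m2"),
    hap1 = c("A", "A"), hap2 = c("B", "A"))
  base_lr <- classify_samples(g, tr)$lr
  # add a marker with identical frequencies in both populations
  freqs3 <- dplyr::bind_rows(
    tr$counts %>%
      dplyr::transmute(marker_id, population, haplotype,
                       frequency = count / n_chrom, n_chrom),
    tibble::tibble(marker_id = "m3", population = c("pop1", "pop1", "pop2", "pop2"),
                   haplotype = c("A", "B", "A", "B"),
                   frequency = rep(c(0.5, 0.5), 2), n_chrom = 10))
  tr3 <- build_training_set(freqs3, alpha = 0)
  g3 <- dplyr::bind_rows(g, tibble::tibble(
    sample_id = "s", marker_id = "m3", hap1 = "A", hap2 = "B"))
  expect_equal(classify_samples(g3, tr3)$lr, base_lr, tolerance = 1e-12)
  # permuting marker order changes nothing
  expect_equal(classify_samples(g[2:1, ], tr)$lr, base_lr, tolerance = 1e-12)
})

test_that("pseudocounts keep unseen haplotypes finite; alpha = 0 does not", {
  tr1 <- worked_training(alpha = 1)
  tr0 <- worked_training(alpha = 0)
  g <- tibble::tibble(sample_id = "s", marker_id = "m1",
                      hap1 = "Z", hap2 = "Z")  # never seen in training
  expect_true(is.finite(genotype_log_likelihood(g, tr1, "pop1")))
  expect_equal(genotype_log_likelihood(g, tr0, "pop1"), -Inf)
})

test_that("training requires a common population set and count provenance", {
  freqs <- tibble::tibble(
    marker_id = c("m1", "m1", "m2"), population = c("A", "B", "A"),
    haplotype = "x", frequency = 1, n_chrom = 10)
  expect_error(build_training_set(freqs), "same population")
  no_n <- tibble::tibble(marker_id = "m1", population = "A",
                         haplotype = "x", frequency = 1)
  expect_error(build_training_set(no_n), "n_chrom")
  expect_s3_class(build_training_set(no_n, n_chrom = 10), "aim_training")
})

test_that("blind trials are perfect on separable populations", {
  g <- make_separable_genotypes()
  res <- blind_trial(g, n_holdout = 10, seed = 99)
  expect_equal(res$accuracy, 1)
  expect_equal(nrow(res$results), 10)
  expect_error(blind_trial(g, n_holdout = 60, seed = 1), "smaller")
})

test_that("blind-trial accuracy is at chance for identical populations", {
  # one shared haplotype pool, arbitrary labels: expect ~50% over seeds
  truth <- list(P1 = c(a = 0.5, b = 0.5), P2 = c(a = 0.5, b = 0.5))
  accs <- vapply(1:60, function(s) {
    g <- sample_genotypes_from_freqs(truth, n_per_pop = 40, seed = 1000 + s)
    blind_trial(g, n_holdout = 4, seed = s)$accuracy
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.12)
})

test_that("accuracy rises with marker divergence", {
  mean_acc <- function(theta, seeds = 1:15) {
    mean(vapply(seeds, function(s) {
      tc <- simulate_panel_cohort(seed = 5000 + 17 * s,
                                  theta_range = c(theta, theta),
                                  samples_per_pop = c(A = 40L, B = 40L))
      g <- marker_genotypes(tc, panel_from_clusters(tc))
      blind_trial(g, n_holdout = 8, seed = s)$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0.05, 0.15, 0.3), mean_acc, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
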