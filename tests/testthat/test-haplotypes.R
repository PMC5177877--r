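two_locus_fixture <- function() {
  # 4 samples covering hom-short, het, mixed and hom-long states
  h1 <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  h2 <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  ch <- make_cohort(h1, h2, rep("P", 4), pos = c(100L, 165L),
                    deltas = c(1L, 4L), cluster_id = c(1L, 1L))
  list(cohort = ch, panel = panel_from_clusters(ch, flank_padding = 28))
}

test_that("phased vectors restrict to unordered marker haplotype pairs", {
  fx <- two_locus_fixture()
  g <- marker_genotypes(fx$cohort, fx$panel)
  expect_equal(nrow(g), 4)  # one row per sample, no missingness
  expect_equal(g$hap1[g$sample_id == "S001"], "00")
  expect_equal(g$hap2[g$sample_id == "S001"], "00")
  expect_setequal(c(g$hap1[g$sample_id == "S002"],
                    g$hap2[g$sample_id == "S002"]), c("00", "10"))
  # base size: span 66 + 2 * 28 = 122; sample 3 carries 10/11 -> 126, 127
  peaks <- ce_peaks(g, fx$panel)
  s3 <- peaks[peaks$sample_id == "S003", ]
  expect_equal(c(s3$size1, s3$size2), c(126, 127))
  expect_equal(s3$n_peaks, 2L)
  hom <- peaks[peaks$sample_id == "S001", ]
  expect_equal(c(hom$size1, hom$size2), c(122, 122))
  expect_equal(hom$n_peaks, 1L)
})

test_that("samples with missing phase are dropped marker-wise", {
  fx <- two_locus_fixture()
  ch <- fx$cohort
  ch$hap1[2, 1] <- NA_integer_
  expect_message(g <- marker_genotypes(ch, fx$panel), "dropped 1")
  expect_equal(nrow(g), 3)
  expect_false("S002" %in% g$sample_id)
})

test_that("peak encoding and genotype calling are mutually inverse", {
  fx <- two_locus_fixture()
  sm <- fx$panel$size_map[[1]]
  haps <- sm$haplotype
  # exhaustive over all unordered pairs of the 4 haplotypes
  pairs <- expand.grid(a = haps, b = haps, stringsAsFactors = FALSE)
  g <- tibble::tibble(
    sample_id = sprintf("X%02d", seq_len(nrow(pairs))),
    population = "P",
    marker_id = fx$panel$marker_id[1],
    hap1 = pmin(pairs$a, pairs$b),
    hap2 = pmax(pairs$a, pairs$b)
  )
  called <- call_genotypes_from_peaks(ce_peaks(g, fx$panel), fx$panel)
  expect_equal(called$hap1, g$hap1)
  expect_equal(called$hap2, g$hap2)
  # a size in the map but unobserved in data is still callable
  one <- tibble::tibble(marker_id = fx$panel$marker_id[1],
                        size1 = 123, size2 = 123)
  expect_equal(call_genotypes_from_peaks(one, fx$panel)$hap1, "10")
  # off-ladder size is refused
  bad <- tibble::tibble(marker_id = fx$panel$marker_id[1],
                        size1 = 122, size2 = 125)
  expect_error(call_genotypes_from_peaks(bad, fx$panel), "off-ladder")
})

test_that("round trip holds exhaustively for a 3-locus marker", {
  h <- matrix(0L, 2, 3)
  ch <- make_cohort(h, h, c("P", "P"), pos = c(100L, 150L, 220L),
                    deltas = c(1L, 2L, 4L), cluster_id = c(1L, 1L, 1L))
  panel <- panel_from_clusters(ch)
  haps <- panel$size_map[[1]]$haplotype
  pairs <- expand.grid(a = haps, b = haps, stringsAsFactors = FALSE)
  g <- tibble::tibble(
    sample_id = sprintf("X%02d", seq_len(nrow(pairs))),
    marker_id = panel$marker_id[1],
    hap1 = pmin(pairs$a, pairs$b), hap2 = pmax(pairs$a, pairs$b))
  called <- call_genotypes_from_peaks(ce_peaks(g, panel), panel)
  expect_equal(called[c("hap1", "hap2")], g[c("hap1", "hap2")])
})

test_that("degenerate size maps are refused for peak work", {
  h1 <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  ch <- make_cohort(h1, h1, rep("P", 4), pos = c(100L, 150L),
                    deltas = c(2L, 2L), cluster_id = c(1L, 1L))
  panel <- panel_from_clusters(ch)
  g <- marker_genotypes(ch, panel)
  expect_error(ce_peaks(g, panel), "degenerate")
})

test_that("haplotype frequencies are exact chromosome counts", {
  g <- tibble::tibble(
    sample_id = sprintf("S%d", 1:4),
    population = "P",
    marker_id = "M1",
    hap1 = c("A", "A", "A", "B"),
    hap2 = c("A", "B", "B", "B")
  )
  f <- count_haplotype_frequencies(g)
  expect_equal(f$frequency[f$haplotype == "A"], 0.5)
  expect_equal(f$frequency[f$haplotype == "B"], 0.5)
  expect_equal(unique(f$n_chrom), 8L)
  # a single homozygous sample
  f1 <- count_haplotype_frequencies(g[1, ])
  expect_equal(f1$frequency, 1)
  # permutation invariance
  set.seed(2)
  f_perm <- count_haplotype_frequencies(g[sample(4), ])
  expect_equal(dplyr::arrange(f_perm, haplotype), dplyr::arrange(f, haplotype))
})

test_that("frequency rows always sum to one and converge with n", {
  truth <- list(P1 = c(a = 0.55, b = 0.3, c = 0.15),
                P2 = c(a = 0.1, b = 0.2, c = 0.7))
  g <- sample_genotypes_from_freqs(truth, n_per_pop = 500, seed = 31)
  f <- count_haplotype_frequencies(g)
  sums <- f %>%
    dplyr::group_by(population) %>%
    dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  for (pop in names(truth)) {
    got <- f$frequency[f$population == pop][match(names(truth[[pop]]),
                        f$haplotype[f$population == pop])]
    expect_lt(max(abs(got - truth[[pop]])), 0.05)
  }
})
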