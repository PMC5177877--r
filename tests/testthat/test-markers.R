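table1_panel <- function() {
  read_panel_table(
    system.file("extdata", "panel_table1.tsv", package = "multindel"))
}

test_that("greedy chaining groups by adjacent gap, not total span", {
  # the published 65-bp pair forms one group
  loci <- tibble::tibble(rsid = c("a", "b"), chrom = "12",
                         pos = c(111390389L, 111390454L))
  g <- cluster_candidates(loci)
  expect_equal(unique(g$candidate_id), 1L)
  expect_equal(diff(g$pos), 65L)
  # 400 bp apart: no marker
  far <- tibble::tibble(rsid = c("a", "b"), chrom = "1",
                        pos = c(1000L, 1400L))
  expect_equal(nrow(cluster_candidates(far)), 0)
  # 7 loci whose adjacent gaps are all small but whose span exceeds 250
  pos52 <- c(32608168L, 32608178L, 32608282L, 32608334L, 32608357L,
             32608392L, 32608459L)
  g52 <- cluster_candidates(tibble::tibble(
    rsid = sprintf("r%d", 1:7), chrom = "6", pos = pos52))
  expect_equal(diff(g52$pos), c(10L, 104L, 52L, 23L, 35L, 67L))
  expect_equal(unique(g52$candidate_id), 1L)
  expect_gt(max(g52$pos) - min(g52$pos), 250)
  # chromosome change always breaks a chain
  cross <- tibble::tibble(rsid = c("a", "b"), chrom = c("1", "2"),
                          pos = c(100L, 150L))
  expect_equal(nrow(cluster_candidates(cross)), 0)
})

test_that("haplotype enumeration counts chromosomes exactly", {
  # 4 samples, 2 loci; phased vectors chosen to show {00, 10, 11}
  h1 <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  h2 <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(1L, 1L))
  ch <- make_cohort(h1, h2, rep("P", 4), pos = c(100L, 160L),
                    deltas = c(1L, 4L))
  haps <- enumerate_haplotypes(ch, ch$loci)
  expect_equal(nrow(haps), 3)
  expect_equal(sum(haps$count), 2 * 4)
  expect_equal(haps$count[haps$haplotype == "00"], 4L)
  expect_equal(haps$count[haps$haplotype == "10"], 2L)
  expect_equal(haps$count[haps$haplotype == "11"], 2L)
  expect_error(enumerate_haplotypes(ch, tibble::tibble(rsid = "nope")),
               "absent")
})

test_that("size maps implement the amplicon-length arithmetic", {
  m5 <- tibble::tibble(delta = c(1L, 4L))
  sm <- compute_size_map(m5, 122)
  expect_equal(sm$size[match(c("00", "01", "10", "11"), sm$haplotype)],
               c(122, 126, 123, 127))
  # observed subset of the published marker: three haplotypes
  expect_setequal(sm$size[sm$haplotype %in% c("00", "01", "11")],
                  c(122, 126, 127))
  single <- compute_size_map(tibble::tibble(delta = 3L), 100)
  expect_setequal(single$size, c(100, 103))
  expect_error(compute_size_map(m5, 0), "positive")
})

test_that("size degeneracy is detected exactly when subset sums collide", {
  twin <- compute_size_map(tibble::tibble(delta = c(2L, 2L)), 100)
  coll <- check_size_degeneracy(twin)
  expect_equal(nrow(coll), 1)
  expect_setequal(c(coll$haplotype_a, coll$haplotype_b), c("01", "10"))
  # restricted to observed haplotypes that avoid the collision: clean
  expect_equal(nrow(check_size_degeneracy(twin, c("00", "01", "11"))), 0)
  distinct_deltas <- compute_size_map(tibble::tibble(delta = c(1L, 4L)), 100)
  expect_equal(nrow(check_size_degeneracy(distinct_deltas)), 0)
})

test_that("panel formation recovers planted clusters and rejects decoys", {
  ch <- make_planted_cohort()
  panel <- build_panel(ch, screen = NULL)
  expect_equal(nrow(panel), 12)
  # recovered markers are exactly the planted clusters
  planted <- ch$loci[ch$loci$cluster_id <= 12, ]
  expect_setequal(panel_loci(panel)$rsid, planted$rsid)
  rej <- attr(panel, "rejected")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("^only 1 haplotype", rej$reason)))
  expect_true(any(grepl("^max observed amplicon", rej$reason)))
  expect_true(any(grepl("collision", rej$reason)))
  # invariant to input locus order: a shuffled cohort gives the same panel
  set.seed(1)
  perm <- sample(nrow(ch$loci))
  shuffled <- ch
  shuffled$loci <- ch$loci[perm, ][order(ch$loci$chrom[perm],
                                         ch$loci$pos[perm]), ]
  expect_equal(build_panel(shuffled, screen = NULL), panel)
})

test_that("the amplicon cap is a strict inequality", {
  # 2-locus marker, span 101, observed haplotypes 00 and 11 (deltas 1+2)
  h1 <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  h2 <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  ch <- make_cohort(h1, h2, c("P", "P"), pos = c(1000L, 1100L),
                    deltas = c(1L, 2L))
  # max size = 101 + 2f + 3; f = 97.5 -> 299 kept, f = 98 -> 300 dropped
  expect_equal(nrow(build_panel(ch, NULL, flank_padding = 97.5)), 1)
  expect_equal(nrow(build_panel(ch, NULL, flank_padding = 98)), 0)
})

test_that("an empty candidate list yields an empty panel without error", {
  cfg <- sim_config(seed = 2, n_loci = 10, samples_per_pop = 4,
                    cluster_fraction = 0)
  ch <- simulate_tiered_cohort(cfg)
  sc <- screen_loci(ch)
  sc$pass <- FALSE
  panel <- build_panel(ch, sc)
  expect_s3_class(panel, "indel_panel")
  expect_equal(nrow(panel), 0)
})

test_that("the published panel is reproduced from its own fixture", {
  panel <- table1_panel()
  loci <- panel_loci(panel)
  regrouped <- cluster_candidates(loci)
  # greedy chaining on the pooled loci reproduces the printed memberships
  key <- split(regrouped$rsid, regrouped$candidate_id)
  want <- split(loci$rsid, loci$marker_id)
  expect_setequal(unname(vapply(key, paste, character(1), collapse = ",")),
                  unname(vapply(want, paste, character(1), collapse = ",")))
  # every adjacent gap under 250
  max_gap <- max(vapply(panel$loci, function(m) max(diff(m$pos)), numeric(1)))
  expect_lt(max_gap, 250)
  # with the published amplicon sizes as bases, all haplotype sizes < 300
  amp <- read_amplicon_table(
    system.file("extdata", "table2_amplicons.tsv", package = "multindel"))
  sizes <- setNames(amp$amplicon_size, amp$marker_id)
  panel2 <- read_panel_table(
    system.file("extdata", "panel_table1.tsv", package = "multindel"),
    base_sizes = sizes)
  all_sizes <- unlist(lapply(panel2$size_map, function(sm) sm$size))
  expect_lt(max(all_sizes), 300)
})
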