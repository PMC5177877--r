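#' Run the full marker-discovery and validation pipeline
#'
#' Executes the stages in dependency order, communicating only through
#' files in the documented formats so every stage is independently
#' re-runnable: simulate a tiered cohort, screen loci with the two-tier
#' FST rule, assemble the multi-InDel panel, count haplotype frequencies,
#' run the blind-trial classifier, the no-admixture clustering scan with
#' delta-K selection, and genotype PCA. Every output file is listed in a
#' machine-readable manifest with an MD5 content hash; re-running with the
#' same configuration reproduces identical hashes. If the screen starves
#' the panel (no marker survives), the validation stages are skipped with
#' a notice and the manifest records the empty panel.
#'
#' @param out_dir Run directory (created if needed).
#' @param sim A [sim_config()] (carries the master seed).
#' @param sub_tier Focal tier for the sub-population criterion.
#' @param t_continental,t_sub Screen thresholds (strict).
#' @param max_gap,max_amplicon,flank_padding Panel formation parameters
#'   (see [build_panel()]).
#' @param validation_pops Two population labels used for the validation
#'   stages (frequency counting, blind trial, clustering, PCA); defaults
#'   to the first two sub-populations of `sub_tier`.
#' @param n_holdout Blind-trial holdout size.
#' @param alpha Classifier pseudocount.
#' @param k_range,replicates,burn_in,kept Clustering-scan parameters.
#' @return Invisibly, a list with the `manifest` tibble (`file`, `md5`),
#'   stage objects (`panel`, `screen`, `selection`, ...) and per-stage
#'   record counts.
#' @export
run_pipeline <- function(out_dir, sim,
                         sub_tier = "EAS",
                         t_continental = 0.4, t_sub = 0.15,
                         max_gap = 250, max_amplicon = 300,
                         flank_padding = 30,
                         validation_pops = NULL,
                         n_holdout = 10, alpha = 1,
                         k_range = 1:4, replicates = 3,
                         burn_in = 1000, kept = 1000) {
  stopifnot(inherits(sim, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  written <- character()
  note <- function(fmt, ...) inform(sprintf(fmt, ...))

  # stage 1: simulate
  cohort <- simulate_tiered_cohort(sim)
  write_cohort_vcf(cohort, path("cohort.vcf"), path("samples.tsv"))
  written <- c(written, "cohort.vcf", "samples.tsv")
  note("simulate: %d samples, %d loci", nrow(cohort$samples), nrow(cohort$loci))

  # stage 2: FST screen
  screen <- screen_loci(cohort, sub_tier = sub_tier,
                        t_continental = t_continental, t_sub = t_sub)
  readr::write_tsv(screen, path("screen.tsv"), progress = FALSE)
  written <- c(written, "screen.tsv")
  note("scan: %d of %d loci pass the two-tier screen",
       sum(screen$pass), nrow(screen))

  # stage 3: panel formation
  panel <- build_panel(cohort, screen, max_gap = max_gap,
                       max_amplicon = max_amplicon,
                       flank_padding = flank_padding)
  note("build-panel: %d markers", nrow(panel))
  counts <- list(n_loci = nrow(cohort$loci), n_pass = sum(screen$pass),
                 n_markers = nrow(panel))
  result <- list(cohort = cohort, screen = screen, panel = panel,
                 counts = counts)

  if (nrow(panel) == 0L) {
    note("build-panel: empty panel; skipping validation stages")
  } else {
    write_panel_table(panel, path("panel.tsv"))
    write_panel_bed(panel, path("panel.bed"))
    write_size_maps_json(panel, path("size_maps.json"))
    written <- c(written, "panel.tsv", "panel.bed", "size_maps.json")

    if (is.null(validation_pops)) {
      validation_pops <- head(
        unique(cohort$samples$population[cohort$samples$tier == sub_tier]), 2L)
    }
    target <- subset_cohort(cohort,
                            cohort$samples$population %in% validation_pops)

    # stage 4: haplotype frequencies by counting
    genos <- marker_genotypes(target, panel)
    freqs <- count_haplotype_frequencies(genos)
    write_frequency_tables(freqs, path("frequencies"))
    written <- c(written,
                 file.path("frequencies",
                           paste0("marker_", sort(panel$marker_id), ".csv")))
    note("frequencies: %d marker-population rows",
         nrow(distinct(freqs, .data$marker_id, .data$population)))

    # stage 5: classification and blind trial
    training <- build_training_set(freqs, alpha = alpha)
    assign_tbl <- classify_samples(genos, training)
    readr::write_tsv(assign_tbl, path("assignments.tsv"), progress = FALSE)
    trial <- blind_trial(genos, n_holdout = n_holdout,
                         seed = sim$seed + 1L, alpha = alpha)
    readr::write_tsv(trial$results, path("blind_trial.tsv"), progress = FALSE)
    written <- c(written, "assignments.tsv", "blind_trial.tsv")
    note("blind-trial: accuracy %.2f on %d holdouts",
         trial$accuracy, n_holdout)

    # stage 6: clustering scan with delta-K
    scan <- structure_scan(genos, k_range = k_range, replicates = replicates,
                           burn_in = burn_in, kept = kept,
                           seed = sim$seed + 2L)
    readr::write_tsv(tidy(scan), path("structure_lnp.tsv"), progress = FALSE)
    readr::write_tsv(scan$selection$table, path("delta_k.tsv"),
                     progress = FALSE)
    best_runs <- scan$runs[scan$runs$K == scan$selection$optimum_K, ]
    if (nrow(best_runs) && scan$selection$optimum_K > 1) {
      q <- align_replicates(best_runs$fit)$mean_posterior
      q_tbl <- as_tibble(q, .name_repair = ~paste0("cluster", seq_along(.x)))
      q_tbl <- bind_cols(tibble(sample_id = rownames(q)), q_tbl)
      readr::write_tsv(q_tbl, path("q_matrix.tsv"), progress = FALSE)
      written <- c(written, "q_matrix.tsv")
    }
    written <- c(written, "structure_lnp.tsv", "delta_k.tsv")
    note("structure: optimum K = %d (%s)",
         scan$selection$optimum_K, scan$selection$method)

    # stage 7: PCA
    pca <- pca_genotypes(genos)
    readr::write_tsv(pca$scores, path("pca.tsv"), progress = FALSE)
    written <- c(written, "pca.tsv")

    result <- c(result, list(
      genotypes = genos, frequencies = freqs, assignments = assign_tbl,
      blind = trial, scan = scan, selection = scan$selection, pca = pca))
  }

  manifest <- tibble(
    file = sort(written),
    md5 = unname(tools::md5sum(path(sort(written))))
  )
  jsonlite::write_json(setNames(as.list(manifest$md5), manifest$file),
                       path("manifest.json"), auto_unbox = TRUE)
  result$manifest <- manifest
  invisible(result)
}
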