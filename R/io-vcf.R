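#' Write a phased cohort to VCF
#'
#' Emits one VCF 4.2 record per locus with phased `GT` fields. Alleles are
#' anchored on a leading base (as in left-aligned InDel records) so the
#' short/long length difference is preserved: `REF = anchor + short`,
#' `ALT = anchor + long`, hence allele index 0 is the short allele. Sample
#' population labels go to a side-car TSV, since VCF has no population field.
#'
#' @param cohort A `phased_cohort`.
#' @param path Output VCF path.
#' @param sample_map_path Output path for the sample-map TSV (columns
#'   `sample_id`, `population`, `tier`); defaults to `<path>.samples.tsv`.
#' @param anchor Single anchor base used to pad empty alleles.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path,
                             sample_map_path = paste0(path, ".samples.tsv"),
                             anchor = "A") {
  stopifnot(inherits(cohort, "phased_cohort"))
  loci <- cohort$loci
  short_seq <- ifelse(loci$short_allele == "-", "", loci$short_allele)
  long_seq <- ifelse(loci$long_allele == "-", "", loci$long_allele)
  ref <- paste0(anchor, short_seq)
  alt <- paste0(anchor, long_seq)

  a1 <- t(cohort$hap1)  # loci x samples
  a2 <- t(cohort$hap2)
  gt <- matrix(paste(ifelse(is.na(a1), ".", a1),
                     ifelse(is.na(a2), ".", a2), sep = "|"),
               nrow = nrow(a1))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=multindel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  body <- paste(loci$chrom, loci$pos, loci$rsid, ref, alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  readr::write_tsv(cohort$samples, sample_map_path, progress = FALSE)
  invisible(path)
}

#' Read a phased InDel cohort from VCF
#'
#' Retains only di-allelic InDel records (single ALT whose length differs
#' from REF) and normalises them to the package's short/long allele-state
#' coding (0 = short, 1 = long) regardless of which allele is the VCF
#' reference. SNP records are dropped silently (they are outside the data
#' model); multi-allelic records are skipped with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_map_path TSV with columns `sample_id`, `population` and
#'   optionally `tier`. Every VCF sample must appear in it.
#' @param unphased How to treat unphased or half-missing heterozygous
#'   genotypes: `"error"` (default; haplotype counting requires phase) or
#'   `"drop"` (set to missing at that locus).
#' @return A `phased_cohort`.
#' @export
read_phased_vcf <- function(path, sample_map_path,
                            unphased = c("error", "drop")) {
  unphased <- match.arg(unphased)
  smap <- readr::read_tsv(sample_map_path, show_col_types = FALSE,
                          progress = FALSE)
  if (!all(c("sample_id", "population") %in% names(smap))) {
    abort("sample map needs columns `sample_id` and `population`.")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort("VCF contains no records.")

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic record(s).", sum(multi)))
  }
  indel <- !multi & nchar(fix$REF) != nchar(fix$ALT)
  if (!any(indel)) abort("no di-allelic InDel records in VCF.")

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[indel, , drop = FALSE]
  fix <- fix[indel, , drop = FALSE]
  vcf_samples <- colnames(gt_raw)
  missing_samples <- setdiff(vcf_samples, smap$sample_id)
  if (length(missing_samples)) {
    abort(paste("samples absent from sample map:",
                paste(missing_samples, collapse = ", ")))
  }

  # strip a shared leading anchor base; the leftover sequences are the alleles
  ref <- fix$REF
  alt <- fix$ALT
  share_anchor <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  ref_seq <- ifelse(share_anchor, substr(ref, 2L, nchar(ref)), ref)
  alt_seq <- ifelse(share_anchor, substr(alt, 2L, nchar(alt)), alt)
  ref_is_short <- nchar(ref_seq) < nchar(alt_seq)
  short_seq <- ifelse(ref_is_short, ref_seq, alt_seq)
  long_seq <- ifelse(ref_is_short, alt_seq, ref_seq)

  loci <- tibble(
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    short_allele = ifelse(short_seq == "", "-", short_seq),
    long_allele = long_seq,
    delta = abs(nchar(alt_seq) - nchar(ref_seq)),
    cluster_id = NA_integer_
  )
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]
  gt_raw <- gt_raw[ord, , drop = FALSE]
  ref_is_short <- ref_is_short[ord]

  as_gt_matrix <- function(x) {
    matrix(suppressWarnings(as.integer(x)),
           nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  }
  sep <- substr(gt_raw, 2L, 2L)
  a1 <- as_gt_matrix(substr(gt_raw, 1L, 1L))
  a2 <- as_gt_matrix(substr(gt_raw, 3L, 3L))
  bad_phase <- !is.na(gt_raw) & (sep == "/" | xor(is.na(a1), is.na(a2)))
  if (any(bad_phase)) {
    if (unphased == "error") {
      abort(sprintf("%d unphased or half-missing genotype(s); use unphased = \"drop\" to exclude them.",
                    sum(bad_phase)))
    }
    a1[bad_phase] <- NA_integer_
    a2[bad_phase] <- NA_integer_
    inform(sprintf("dropped %d unphased genotype(s).", sum(bad_phase)))
  }
  flip <- !ref_is_short  # VCF allele 0 is the long allele at these loci
  a1[flip, ] <- 1L - a1[flip, , drop = FALSE]
  a2[flip, ] <- 1L - a2[flip, , drop = FALSE]

  smap <- smap[match(vcf_samples, smap$sample_id), , drop = FALSE]
  new_phased_cohort(
    samples = smap,
    loci = loci,
    hap1 = t(a1),
    hap2 = t(a2)
  )
}
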