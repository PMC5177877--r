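# multindel

Discovery and validation of **multi-InDel ancestry-informative markers
(AIMs)** — clusters of tightly spaced insertion/deletion polymorphisms
treated as one multi-allelic marker whose alleles are haplotypes, each
observable on routine capillary electrophoresis (CE) as a distinct amplicon
size. Panels of such markers can separate closely related populations
(e.g. ethnic groups within East Asia) with far fewer loci than di-allelic
SNP or InDel panels, which makes them attractive for forensic casework and
for detecting stratification in association studies.

The package implements the full computational workflow:

1. **Simulation** — phased diploid InDel cohorts under a hierarchical
   Balding–Nichols model: population frequencies are Beta-distributed
   around an ancestral frequency *p* with variance *F·p(1−p)*, so the
   expected Weir–Cockerham θ between populations equals *F*. Two tiers
   (continental groups, sub-populations within one group) and tight
   genomic clustering of a configurable fraction of loci.
2. **FST screening** — the per-site Weir–Cockerham (1984)
   variance-component estimator θ = a/(a+b+c), a two-tier threshold screen
   (θ > 0.4 for all continental pairs **and** θ > 0.15 for all
   sub-population pairs, both strict), and the multi-locus estimator
   Σa/Σ(a+b+c) for parameter recovery.
3. **Marker formation** — greedy chaining of screened loci with adjacent
   gaps < 250 bp, haplotype enumeration (≥ 2 observed haplotypes
   required), amplicon-size maps (all-short haplotype ↦ base size, each
   long allele adds its length delta), a < 300 bp amplicon cap and an
   injectivity check so CE genotyping is invertible.
4. **Haplotyping** — phased genotypes ↦ per-marker haplotype pairs ↦ CE
   peak sets, the inverse caller, and haplotype-frequency estimation by
   chromosome counting.
5. **Classification** — a Snipper-style naive-Bayes assigner: per-marker
   Hardy–Weinberg genotype likelihoods from smoothed training frequencies
   (p̃ = (c+α)/(2N+αH)), reporting the ratio of the two highest
   likelihoods, with blind-trial evaluation.
6. **Model-based clustering** — a no-admixture Gibbs sampler (Rcpp) over
   cluster-specific haplotype frequencies with symmetric Dirichlet priors,
   ln P(X|K) estimated as mean − var/2 of the log-likelihood trace (exact
   Dirichlet-multinomial closed form at K = 1), Evanno ΔK model choice,
   replicate label alignment, and haplotype-dosage PCA.

## Worked example

Simulate a target study — two populations (110 + 100 diploid samples, the
size of a typical two-cohort validation study) genotyped at a 12-marker
panel with per-marker θ between 0.15 and 0.4 — then validate the panel:

```r
library(multindel)

cohort <- simulate_panel_cohort(seed = 42,
                                samples_per_pop = c(TIB = 110L, HAN = 100L))
panel  <- panel_from_clusters(cohort)
geno   <- marker_genotypes(cohort, panel)

# blind-trial ancestry assignment (10 holdouts, training recounted without them)
trial <- blind_trial(geno, n_holdout = 10, seed = 7)
trial$accuracy
#> [1] 1
trial$results[1:3, c("sample_id", "best_pop", "truth", "log10_lr")]
#>   sample_id best_pop truth log10_lr
#> 1 S0015     TIB      TIB       8.17
#> 2 S0022     TIB      TIB      11.5
#> 3 S0042     TIB      TIB      10.4

# no-admixture clustering across K = 1..4 with Evanno delta-K selection
scan <- structure_scan(geno, k_range = 1:4, replicates = 3,
                       burn_in = 1000, kept = 1000, seed = 9)
scan$selection
#> <k_selection> optimum K = 2 (delta_K)
#>       K mean_lnP sd_lnP n_rep delta_K
#> 1     1   -5835.   1.00     3   NA
#> 2     2   -4947.   1.87     3  477.
#> 3     3   -4950.   8.29     3    1.12
#> 4     4   -4962.  20.7      3   NA

# genotype PCA: PC1 carries the population split
pca <- pca_genotypes(geno)
glance(pca)
#>   n_samples n_components pve_pc1 pve_pc2
#> 1       210           92   0.213  0.0617
```

All 10 blind samples are assigned to their recorded population with
log10 likelihood ratios around 8–12; ΔK peaks sharply at K = 2 (the true
number of populations); and PC1 explains 21% of genotype variance, the
axis separating the two groups. `autoplot()` methods draw the membership
bar plot, the ΔK profile and the PCA scatter.

A published 12-marker panel ships as plain-text fixtures
(`inst/extdata/panel_table1.tsv` with 37 member InDels and
`table2_amplicons.tsv` with multiplex amplicon sizes) and parses with
`read_panel_table()` / `read_amplicon_table()`. The end-to-end discovery
workflow (simulate → screen → build panel → frequencies → classify →
cluster → PCA, with a hash-stable manifest) is `run_pipeline()`.

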