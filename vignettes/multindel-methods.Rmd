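---
title: "Methods: multi-InDel ancestry-informative marker discovery and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-InDel ancestry-informative marker discovery and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models, estimators and design choices behind the
package, at the level of detail a maintainer or reviewer needs to judge
what the code computes and why.

## The marker class

A *multi-InDel* marker is a run of di-allelic insertion/deletion
polymorphisms so tightly spaced (adjacent gaps under 250 bp here) that a
single short PCR amplicon covers all of them. The allele of the marker is
the *haplotype* — the combination of short/long states across member loci
on one chromosome — and because each long allele adds its own length
difference to the amplicon, haplotypes are read directly off capillary
electrophoresis as distinct fragment sizes. A diploid therefore shows one
or two peaks per marker; no computational phasing is needed in the assay
itself. Formally, with member length differences $\delta_1,\dots,\delta_k$
and a base amplicon size $b$ for the all-short haplotype, haplotype
$h \in \{0,1\}^k$ maps to size $b + \sum_j h_j \delta_j$
(`compute_size_map()`). The map must be injective over the haplotypes that
actually occur — `check_size_degeneracy()` enforces this, since equal
subset sums (e.g. two loci with $\delta = 2$) would make two haplotypes
indistinguishable on the trace.

Within the package, haplotypes are written as allele-state strings in
member-locus order, `"0"` for the short and `"1"` for the long allele
(so `"01"` at a 2-InDel marker means short at the first, long at the
second locus). Frequency tables may be keyed either by these strings or by
amplicon sizes; the two namespaces are never mixed within one table.

## The synthetic cohort generator

No genotypes are distributed with the marker class's source studies, so
every downstream stage is exercised on simulated cohorts with controlled,
known structure.

**Divergence model.** Population allele frequencies follow the
Balding–Nichols model: given an ancestral frequency $p$ and a fixation
index $F$, each population draws its frequency from
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$, which
has mean $p$ and variance $F\,p(1-p)$. This generator was chosen because
the screen targets Weir–Cockerham $\theta$: the model's $F$ *is* the
expected $\theta$, and the closed-form moments give exact oracles for
tests. `sim_config()` applies it twice — once across continental tiers
(`F_continental`) and once across sub-populations within any multi-member
tier (`F_sub`) — emulating a 1000-Genomes-like layout: five continental
groups, five sub-populations inside the East-Asian analog, with high and
low divergence respectively.

**Genotypes.** Each diploid sample receives two independently drawn
haplotypes, so genotypes are in Hardy–Weinberg equilibrium within each
population by construction (verified by a chi-square goodness-of-fit
property test).

**Clusters and linkage.** A configurable fraction of loci
(`cluster_fraction`) is laid out in runs of 2–7 loci with gaps drawn from
`cluster_gap_range`; the remainder are isolated, 10 kb apart, so the
250-bp chaining rule can be exercised in both directions. Loci within a
cluster share a latent Gaussian factor with loading $\sqrt{r^2}$
(`ld_r2`, default 0.5): a Gaussian-copula construction that leaves every
locus's marginal frequency untouched while making long alleles co-occur on
haplotypes. This yields markers with more than two but usually fewer than
$2^k$ observed haplotypes — the qualitative pattern of real multi-InDel
markers, where one of the four possible 2-locus haplotypes is often
absent. No quantitative LD model for real multi-InDel clusters was
available; `ld_r2 = 0.5` is a free parameter chosen once as a moderate
value, not an estimate.

**Target cohorts.** `simulate_panel_cohort()` builds the validation-study
design directly: two populations (defaults 110 and 100 diploids, a
typical two-cohort study size), 12 planted clusters, each cluster's own
divergence drawn uniformly from `theta_range` (default [0.15, 0.4], the
operating range of a sub-continental panel).

**What the generator does not emulate:** coalescent genealogies,
recombination, mutation, selection, genotyping error, allelic dropout or
stutter. Passing tests therefore demonstrate correctness of the
estimators and decision rules under a clean frequency-divergence model,
not robustness to real-data artifacts.

## FST estimation and the two-tier screen

`wc_theta()` implements the per-site Weir–Cockerham (1984) estimator from
per-population diploid sample sizes $n_i$, long-allele frequencies $p_i$
and observed heterozygote proportions $h_i$: the among-population ($a$),
among-individual ($b$) and within-individual ($c$) variance components
with $\hat\theta = a/(a+b+c)$, using $\bar n$, $n_c$, the weighted mean
frequency, frequency variance $s^2$ and mean heterozygosity $\bar h$.
Estimates may be slightly negative by sampling and are *not* clamped —
they can never pass the screen anyway. When all populations are fixed for
the same allele the estimator is undefined and is returned as `NA` with
reason `"monomorphic"`.

Two numerical points deserve emphasis:

* **Per-locus vs multi-locus.** The mean of per-locus ratios is biased
  downward (the ratio is a concave function of correlated numerator and
  denominator), noticeably so at moderate $F$. For genome-scale parameter
  recovery the package provides `wc_theta_multilocus()`, the ratio of
  *summed* components $\sum a / \sum(a+b+c)$ — the combination Weir and
  Cockerham themselves prescribe — which recovers the generating $F$ of a
  Balding–Nichols simulation within Monte-Carlo error.
* **Feasibility of the all-pairs rule.** The screen passes a locus only if
  $\theta > 0.4$ for *every* pair of the continental groups and
  $\theta > 0.15$ for *every* pair of the focal sub-populations (both
  strict, per `t_continental` / `t_sub`). For five groups the continental
  part is structurally unsatisfiable at a di-allelic locus: five
  frequencies in $[0,1]$ cannot be pairwise separated enough for every
  pairwise $\theta$ to exceed 0.4 (the achievable minimum over the ten
  pairs tops out near 0.2). The rule is kept as specified — it is the
  documented contract, and the thresholds are parameters — but the
  property tests that need a non-trivial passing fraction use a two-tier
  configuration where the event has positive probability. Users screening
  five-group data should expect the binding constraints to be the extreme
  pairs, and may prefer an exists-pair variant by screening pairs
  directly from `pairwise_theta()` output.

Screening decisions are re-verified in the tests by a brute-force oracle
that recomputes every pairwise $\theta$ from raw genotype counts through
an independently written routine.

## Marker formation

`cluster_candidates()` chains sorted loci greedily: a locus joins the
current group iff it is on the same chromosome within `max_gap` (250 bp)
of the *previous member*. The spacing rule is deliberately read as an
adjacent-pair gap, not a total span: the shipped reference panel contains
a seven-InDel marker spanning 291 bp whose adjacent gaps are all at most
104 bp, so the adjacency reading is the only one consistent with that
panel. Greedy left-to-right chaining (rather than optimizing over
alternative partitions) matches a scan over sorted positions and is
deterministic. Singleton groups are discarded — a multi-InDel has at
least two members by definition.

`build_panel()` then applies the formation filters per candidate: at
least two observed haplotypes (a haplotype "exists" if seen on one or
more chromosomes; no frequency floor), largest *observed* amplicon
strictly under `max_amplicon` (300 bp), and no amplicon-size collision
among observed haplotypes. The base amplicon size is modeled as the
marker's reference span plus `2 * flank_padding` (default 30 bp per
side), a stand-in for primer placement, which is out of scope; when a
measured amplicon size is available (as in the shipped size table) it
overrides the model via `base_sizes`. Rejected candidates are kept with
reasons as an attribute so filter attrition is auditable.

`panel_from_clusters()` bypasses the filters and turns a simulated
cohort's planted clusters directly into a panel — the situation of a
fixed, already-designed panel genotyped in new cohorts, which is what the
validation stages model.

## Haplotype frequencies and the classifier

Frequencies are maximum-likelihood chromosome counts:
$\hat f_h = c_h / 2N$ per marker and population, with samples missing
phase at a marker excluded marker-wise and never imputed. No smoothing is
applied at this stage — smoothing is the classifier's concern, keeping
the counting estimator exact. Every frequency row must sum to 1 within
$10^{-9}$; violations on read are hard errors naming the marker and
population.

The classifier is a naive-Bayes assigner in the style of forensic
ancestry tools: markers independent (the reference panel sits on five
chromosomes; loose linkage is assumed), Hardy–Weinberg within each
reference population, so a homozygote $(i,i)$ contributes $\tilde p_i^2$
and a heterozygote $(i,j)$ contributes $2\tilde p_i \tilde p_j$, with
smoothed frequencies
$\tilde p_h = (c_h + \alpha)/(2N + \alpha H)$, where $H$ is the number of
haplotype classes the marker has in training. The pseudocount defaults to
$\alpha = 1$ (Laplace) because the reference tool's exact smoothing is
not published; $\alpha = 0$ reproduces raw counting and is exposed.
Unseen haplotypes get the $\alpha$-floor, so likelihoods stay finite for
any genotype whenever $\alpha > 0$. Assignment is the arg-max population;
the reported strength is the ratio of the two highest likelihoods
(`lr`, also as `log10_lr`), with posterior probabilities under a uniform
prior alongside. A tie within $10^{-12}$ in log space yields status
`"tie"` rather than a forced call.

`blind_trial()` mirrors a holdout validation: `n_holdout` samples are
drawn uniformly from the pooled cohort (without stratification — the
procedure being emulated states only "randomly chosen"), training
frequencies are recounted *without* them, and accuracy is the fraction of
holdouts assigned to their recorded population.

## No-admixture clustering and K selection

`gibbs_no_admixture()` implements the classical no-admixture clustering
model: each individual originates wholly from one of $K$ clusters; each
cluster has its own haplotype-frequency vector per marker with a
symmetric Dirichlet($\lambda$) prior ($\lambda = 1$ default); genotype
probabilities are Hardy–Weinberg within a cluster. Haplotypes are the
allelic unit — one multi-allelic locus per marker — matching how the
panel is genotyped. The Gibbs sampler alternates
(1) frequencies $\sim$ Dirichlet($\lambda$ + counts) given assignments and
(2) assignments $\sim$ categorical given frequencies, and records the data
log-likelihood $\log P(X \mid z, P)$ at every kept iteration. The
*uncorrelated*-frequencies prior is implemented; the correlated
$F$-model adds substantial machinery without changing what a desk-scale
validation can show, and the prior update is isolated in one place should
it be swapped.

Label switching is handled at two levels: within a run, each kept
iteration's labels are aligned to the first kept iteration by a greedy
maximum-overlap permutation before posteriors are accumulated; across
replicate runs, `align_replicates()` aligns posteriors to the first run
exhaustively over all $K!$ permutations (cheap for the $K \le 7$ range
used here).

**Model evidence.** $\ln P(X|K)$ is estimated from the kept trace as
$\overline{L} - \mathrm{Var}(L)/2$ (`estimate_lnP()`), the standard
harmonic-style approximation used with this sampler family. At $K = 1$
the marginal likelihood has an exact closed form — a product of
Dirichlet-multinomials over markers, times 2 per heterozygote for the
unordered pair — and the fit reports that exact value as its `lnP`
(verified in tests against an independent Pólya-urn factorization to
$10^{-9}$). Because the exact value and the trace approximation sit on
systematically different levels, `structure_scan()` compares K values on
the trace-estimator scale (`lnP_trace`) for *every* K, and the exact
K = 1 value is kept as a validation quantity.

**Choosing K.** `evanno_delta_k()` computes
$\Delta K = |\overline{L}(K{+}1) - 2\overline{L}(K) + \overline{L}(K{-}1)| / \mathrm{sd}\,L(K)$
for interior K with nonzero replicate s.d., and selects its arg-max.
$\Delta K$ cannot evaluate $K = 1$, and on panmictic data the trace
estimator drifts mildly upward with K, so a bare arg-max over-reports
structure. The selection therefore applies a noise gate first: $\Delta K$
is consulted only when the best mean $\ln P(X|K)$ improves on the
smallest K by more than three times the largest replicate standard
deviation; otherwise the data show no evidence of structure and the
smallest K is reported (method `"max_lnP"`). The same fallback covers
degenerate inputs (fewer than three K values, or no defined interior
$\Delta K$).

**Problem sizes.** The sampler is compiled (Rcpp) and uses R's RNG, so
`set.seed()` makes runs bit-reproducible. Package defaults are 5,000
burn-in and 5,000 kept iterations — the scale at which the acceptance
analysis runs K = 1..7 with five replicates on a 210-sample, 12-marker
cohort in a few minutes — while the property tests use smaller cohorts
(60–120 samples) and shorter chains (300–500 iterations), sizes chosen so
the whole suite stays fast; longer chains are accepted via `burn_in` /
`kept` for users who want production-length runs.

## Genotype PCA

`pca_genotypes()` encodes each marker as haplotype-dosage columns (copies
of each haplotype carried: 0, 1, 2), drops one reference column per
marker to remove the exact within-marker collinearity (dosages sum to 2),
mean-centres and eigendecomposes the covariance. Samples missing a marker
are mean-imputed for that marker's columns (a plotting convenience; the
simulators produce no missingness). Explained-variance fractions sum to
1; a constant matrix is handled explicitly with zero scores rather than
an error.

## Degenerate inputs and numerical conventions

* Coordinates are 1-based at every interface (panel tables, VCF); the
  BED export is 0-based half-open as that format requires.
* VCF records are normalised to short/long coding irrespective of which
  allele is the reference; multi-allelic records are skipped with a
  warning, SNPs are dropped silently (outside the data model), unphased
  heterozygotes are a hard error by default with an opt-in `"drop"` mode
  (haplotype counting is only exact with phase), and missing genotypes
  are excluded marker-wise, never imputed.
* Frequency-table row sums are checked to $10^{-9}$; posterior rows from
  the sampler sum to 1 by construction and are asserted to $10^{-9}$ in
  tests; classifier ties break at $10^{-12}$ in log space; oracle
  agreement for the FST estimator is asserted at $10^{-12}$.
* All stochastic entry points take explicit seeds; `structure_scan()`
  derives replicate seeds from its master seed, and `run_pipeline()`
  derives stage seeds from the simulation seed, so a configuration
  reproduces a byte-identical run directory (asserted via MD5 manifest).

## Known limitations

* The generator's clean Balding–Nichols world contains no genotyping
  error, dropout, stutter or null alleles; classifier and clustering
  accuracies measured here are upper bounds relative to lab data.
* The all-pairs continental screen at $\theta > 0.4$ is infeasible for
  five groups (discussed above); the screen is most useful as specified
  when the continental tier has two or three groups, or with relaxed
  thresholds.
* Haplotype-level (multi-allelic) $\theta$ for assembled markers is not
  used as a filter anywhere; screening is strictly per-InDel.
* The no-admixture model reports assignment posteriors, not admixture
  proportions; individuals of genuinely mixed ancestry will be forced
  toward one cluster.
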