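---
title: "Divergence scans for RAD-seq genotypes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence scans for RAD-seq genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

radscan contrasts **local adaptation** with **speciation** in a crossed
sampling design: three sympatric species collected at each of three
locations, fourteen diploids per species-by-location cell (126 individuals),
genotyped at tens of thousands of anonymous RAD SNPs. Divergence along the
location axis (within species) reflects adaptation and drift across
geography; divergence along the species axis (within locations) reflects
speciation. Both axes sit on a background multilocus F\_st of only ~0.004,
so everything in the package is built for the regime where the signal is a
thin tail on a near-zero distribution: per-locus estimates are kept (with
their legitimate negative values), multilocus summaries are ratios of sums,
and every significance statement is calibrated by simulation rather than
asymptotics.

## The F\_st engine

`wc_fst()` implements the Weir–Cockerham ANOVA estimator for diploids:
per-locus variance components $a$ (among groups), $b$ (among individuals
within groups) and $c$ (within individuals), with

$$\hat F_{st} = \frac{a}{a+b+c}, \qquad
  \hat F_{st}^{\text{multi}} = \frac{\sum_\ell a_\ell}{\sum_\ell (a_\ell+b_\ell+c_\ell)}.$$

A locus enters the analysis with the groups that have at least two
non-missing genotypes there, and is *defined* when at least two such groups
remain and the total variance is non-zero. Undefined loci are flagged and
excluded from the sums, never silently zeroed. Negative per-locus estimates
are preserved throughout — the percentile machinery depends on them (the
motivating study's 60th-percentile bin edge is negative).

The estimator is verified in two independent ways: exhaustively against a
mean-squares ANOVA oracle on every 2-group configuration of up to six
individuals, and behaviorally (fixed differences give exactly 1; identical
groups give non-positive values; permuted labels give |F\_st| < 0.005).

`diversity_summary()` reports per-group observed heterozygosity, unbiased
expected heterozygosity ($\frac{2n}{2n-1}\,2\hat p\hat q$ per locus),
F\_is, and π. Note that π here is per retained SNP site (the mean unbiased
He across SNP sites); a per-nucleotide π would require the invariant sites,
which RAD genotype tables do not carry.

## Filters

The RAD-specific filters mirror standard genotype-call curation:

* `filter_loci_by_coverage()` works at the **stack** level using the
  per-stack mean depth: a stack is retained iff at least `min_groups`
  grouping units have at least `min_inds` individuals at mean depth
  `>= min_depth` (inclusive). The two canonical settings are 10x in ≥15
  individuals per location in ≥2 locations (pooled analyses) and 10x in ≥5
  per cell in ≥7 cells (per-sample analyses). Whether "coverage ≥10x"
  applies per SNP or per stack is ambiguous in the field's descriptions; the
  per-stack mean was chosen because stacks are the unit the assembler
  reports coverage for, and a stack passes or fails as a unit.
* `filter_rare_alleles()` removes loci whose globally minor allele is
  carried by at most one individual in *every* grouping unit; monomorphic
  loci pass (they are handled by the F\_st definedness rules).
* `filter_heterozygosity()` removes loci with observed heterozygote
  fraction strictly above 0.5 (paralog-collapse signature; required before
  LD-network analysis).
* `select_first_snp_per_stack()` keeps the smallest-offset SNP per stack,
  removing the within-stack redundancy (~1.8 SNPs per stack) wherever
  linked SNPs would double-count signal.
* `filter_individuals_by_missingness()` drops individuals with strictly
  more than 20% missing calls (default), used before tree building.

All filters are pure and idempotent; the default pipeline order is
coverage → rare-allele → heterozygosity → first-SNP.

## The island-model null

`run_scenario()` is a forward Wright–Fisher island model at the frequency
level: `n_demes` demes of `deme_size` diploids; per generation, migration
($p_i' = (1-m)p_i + m\,\overline{p_{-i}}$, i.e. the total emigration
probability $m$ splits equally among the other demes), then binomial drift
with $2N$ trials, then symmetric mutation at rate μ. Genotypes are realized
only at sampling, as Hardy–Weinberg pairs — statistically equivalent to an
individual-based model for unlinked loci and orders of magnitude faster.

**Census convention.** Datasets are sampled at the *post-migration census
point*: individuals are observed after the generation's migrants have joined
their demes, before reproduction regenerates drift deviations. The
distinction matters at high migration. With $\lambda = 1 - m\,d/(d-1)$, the
stationary variance ratio is $(1/2N)/(1-\lambda^2)$ just after
reproduction but $\lambda^2/(2N(1-\lambda^2))$ just after migration. At the
panmictic setting ($d=9$, $N=1000$, $m=0.5$) these are ~6.2e-4 versus
~1.1e-4 — only the post-migration census is consistent with the printed
behavior of the individual-based simulations this module emulates, which
census a generation after applying migration. At the structured setting
($m=0.02$) the two differ by under 5% (~0.0107), comfortably above the
0.0031 benchmark either way.

**Initial frequencies and run length.** Loci start at a common ancestral
frequency drawn Uniform(0.05, 0.95) (all demes identical, so F\_st starts
at 0), keeping most loci polymorphic over the runs. Run lengths are not
fixed a priori: `quasi_stationarity_gens()` monitors the frequency-level
F\_st trajectory on a 2,000-locus probe every 10 generations and stops when
it changes by less than 5% over a 50-generation window (capped, with a
warning, for models like $m=0$ that never stabilize). Strong migration
stabilizes within tens of generations; the structured scenario needs a few
hundred.

## The outlier scan

The scan follows the FDIST logic with an explicitly simulated null:

1. `calibrate_null()` builds an island model with as many demes as the
   comparison has groups and the comparison's sample size, solving the
   migration rate from the census relation
   $\lambda^2 = 2NF/(1+2NF)$ so the null's stationary multilocus F\_st
   matches the observed one (one conservative probe-run refinement; targets
   below 1e-6 are clamped to a near-panmictic null). At least B null locus
   draws (default 200,000) are retained and binned into ≥20 equal-count
   heterozygosity classes.
2. `empirical_pq()` assigns each locus
   $p = (1 + \#\{\text{null in He class} \ge \hat F_{st}\})/(B_{\text{class}}+1)$,
   Benjamini–Hochberg q-values, and flags outliers at $q < 0.2$ (an
   expected FDR of 20%; 0.05 is the stringent setting).
3. `scan_comparisons()` runs one scan per (species, location pair) — the
   nine-comparison design — or one global scan per species;
   `repeated_outliers()` intersects the flags across species, reporting
   repeated (≥2 species) and triple-repeated loci plus the
   shared-consideration ratio, and `randomized_grouping_scan()` reruns
   everything under a random 3×3 relabeling.

Two calibration details carry most of the statistical weight:

* **Missingness matching.** The null applies the scanned data's missing-call
  rate to its own samples. A complete-data null is anti-conservative against
  RAD data: missing calls vary the per-locus usable sample size, which
  widens the tails of the per-locus F\_st sampling distribution even when
  the mean is calibrated. On synthetic data with ~7% missingness the
  complete-data null flagged ~2% of neutral loci; the rate-matched null
  flags none.
* **Granularity and power.** The empirical p cannot go below
  $1/(B_{\text{class}}+1)$, so with BH at $q<0.2$ a solitary perfect
  outlier is only detectable when $B_{\text{class}} \gtrsim 5\times$ the
  number of scanned loci. The default B mirrors the conservatism of the
  Bayesian scanners this test replaces: genome-scale null scans yield
  essentially zero discoveries, and power analyses should scale B with the
  locus count. The prior-odds sensitivity axis of those scanners maps to
  the q-threshold (0.2 vs 0.05) here.

Null ensembles are cached per (group count, sample size, target F\_st
snapped to a 25%-step grid, missingness rate) — the nine comparisons of one
dataset share a design and near-identical background, so one ensemble
serves them all.

## Percentile stratification, clustering, trees

`percentile_stratify()` partitions defined loci by nearest-rank F\_st
percentiles (order statistic at position $\lceil (n+1)p \rceil$, capped at
$n$) into half-open bins [lower, upper), top bin closed. Ties share a bin
by value, so bin counts may deviate from exact tenths, as they do in real
data. The admixture-MCMC clustering the field traditionally runs on these
subsets is replaced by `pca_cluster()` (mean-imputed dosage PCA, k-means
over $k = 1..k_{max}$, silhouette-based selection with $k=1$ reported when
no $k>1$ reaches a mean silhouette of 0.25), and likelihood phylogenetics
by `nj_tree()` on `allele_sharing_distance()` with a locus-resampling
bootstrap. These substitutes answer the same question the originals were
asked — does this SNP stratum separate locations or species? — without
reproducing those tools' model internals; their absolute cluster scores and
supports are not comparable to STRUCTURE or RAxML outputs.

## LD network analysis

`ld_r2_matrix()` uses the squared composite (Burrows-type) genotype
correlation over pairwise-complete individuals — phase is unknown in RAD
genotypes — with pairs sharing <80% of individuals set to undefined.
`build_ld_tree()` sweeps the threshold 1.00 → 0 in steps of 0.01 (the grid
approximates continuous merging; the step is a config knob) and records
single-linkage merge events. At each merge, each constituent cluster of ≥2
loci receives $\lambda = n_{\text{focal}}(\tilde r^2_{\text{before}} -
\tilde r^2_{\text{after}})$; outlier clusters exceed
median(λ) + φ·MAD(λ) (MAD with the 1.4826 consistency constant) and carry
at least $|E|_{\min}$ edges at their merge threshold; SOCs are outlier
clusters with no outlier nested inside. The study's operating point is
φ = 4, $|E|_{\min}$ = 16. `soc_divergence()` then separates the two SOC
aetiologies: group-differentiating clusters (elevated per-SOC F\_st and
PC-centroid separation — admixture LD) versus physically linked but
group-neutral clusters (F\_st ≈ 0, high internal median r² — the inversion
signature).

One numerical caveat found while testing: a λ outlier call is *relative* —
if every merge in a dataset has identical λ (as in exact-tie toy matrices),
median + φ·MAD degenerates and nothing is flagged. Real (sampled) LD
matrices always carry enough jitter to populate the λ distribution; toy
fixtures must too.

## The synthetic generator

`generate_dataset()` emulates the study's genotype calls: ~30,000 stacks
carrying 1–3 SNPs (mean 1.8), ancestral frequencies Beta(0.8, 0.8)
truncated to [0.02, 0.98], a Balding–Nichols hierarchy with the location
step above the species step, HWE genotypes, negative-binomial per-stack
depth (mean 31x), depth-driven (<10x) plus MCAR missingness, and planted
loci (location-divergent, species-divergent, fixed-difference, linked
blocks) recorded in a truth table.

Two calibration choices deserve emphasis:

* The `f_loc` knob is defined as the *realized* pooled among-location
  divergence. Because the species-step deviations average into the pooled
  location frequencies, the location Balding–Nichols step internally uses
  $f_{loc} - f_{sp}/n_{sp}$; with both knobs at the default 0.004 the
  generated among-location multilocus F\_st is 0.004 within the simulation
  CI (checked over ten seeds). The flip side of the shared location step is
  that location divergence is parallel across species by construction —
  which is exactly what lets percentile subsets cluster individuals by
  location across species, as in real data.
* Linked blocks share a latent haplotype; allele copies flip with
  probability $e = (1-r_2^{1/4})/2$, giving block r² near the target
  (realized median within [0.45, 0.75] of a 0.6 target across seeds).

What the generator does *not* emulate: genotyping error, null alleles,
allele dropout, stack over/under-merging, linkage beyond the planted
blocks, and selection dynamics (planting is static). Tests passing on
synthetic data therefore validate the pipeline's statistics, not its
robustness to assembly artifacts.

## Problem sizes used in the checks

The packaged test suite exercises the simulation benchmarks at reduced
scale — 8,000 loci for the two scenario means (30 datasets each), 20,000
loci for the null outlier scan, 800-stack generator runs for the
planted-outlier recovery — sizes at which the multilocus estimates are
already precise to a few times 1e-4. `scripts/acceptance.R` reruns the
same computations at the full 80,000-locus, 30-dataset scale.

## Known limitations

* The LD matrix is dense and quadratic in loci; beyond ~10,000 loci it is
  impractical (pre-filter and take one SNP per stack first).
* Null calibration assumes the comparison's groups are exchangeable demes
  of a symmetric island model; strong asymmetric gene flow or unequal
  sample sizes are approximated by the rounded per-group mean.
* The scan's empirical-p floor bounds attainable q-values; see the
  granularity note above before interpreting "zero outliers" on very large
  SNP panels with small B.
* `pca_cluster()`'s silhouette selection cannot report hierarchical or
  admixed structure; it answers "how many well-separated groups", nothing
  finer.
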