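---
title: "Mixed-model GWAS, meta-analysis, and LD-aware region prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model GWAS, meta-analysis, and LD-aware region prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gwasregions` implements a complete post-GWAS analysis for two-cohort
(two-breed) studies of quantitative and binary metabolic traits, of the kind
used to dissect equine metabolic syndrome (EMS) in high-risk pony and horse
breeds. This vignette explains the statistical model at each stage, the
tunable parameters and their defaults, what the bundled simulator does and
does not emulate, and the design choices made where the methodology was
genuinely open.

## The analysis model

### Phenotype preparation

Each quantitative trait is first brought to approximate normality. The
canonical panel (`ems_traits()`) fixes the transform per trait — square root
for adiponectin, leptin and NEFA; natural log for insulin, INS-OST,
triglycerides and ACTH; identity for glucose, GLU-OST and the two
morphometric ratios — and `transform_mode = "auto"` instead selects the
member of {identity, sqrt, log} maximizing the Shapiro–Wilk W statistic
(domains permitting; n is capped at 5,000 by deterministic subsampling
because the W approximation is defined up to that size).

Known confounders are then removed with a random-intercept linear mixed
model, `y = intercept + sex + age + (1 | farm)`, fitted by REML (delegated
to `lme4`). The adjusted trait is the vector of *conditional* residuals:
both the fixed-effect estimates and the farm BLUPs are subtracted, so no
farm-level signal survives into the association scan. Whether the original
analysis subtracted farm BLUPs or only fixed effects is not determinable
from its description; conditional residuals are the `nlme`/`lme4` default
residual type and are the stricter choice, so the package uses them. The
binary laminitis trait is passed through the same linear adjustment on the
observed 0/1 scale and scanned as a quantitative response — a
linear-on-liability treatment that is standard for LMM GWAS when no
logistic mixed model is specified.

### Genotype quality control

Filters run in a fixed order, each seeing the output of the previous step:
samples with call rate ≤ 0.95 are dropped; then SNPs with call rate < 0.90,
minor allele frequency < 1%, and exact Hardy–Weinberg p < 1e-5. The HWE
test is the conditional exact test (enumeration of heterozygote counts
given allele counts), the standard choice for MAF-filtered array data;
monomorphic sites return p = 1 by convention. HWE is computed within
cohort, never pooled across breeds, to avoid Wahlund-effect artifacts.

### Association scan

The scan is an EMMAX-style single-stage linear mixed model. The genetic
relationship matrix is `K = ZZ'/M` over column-standardized dosages
(missing values mean-imputed for this computation only). The null model
`y = Xb + g + e`, `g ~ N(0, s2_g K)`, `e ~ N(0, s2_e I)` is fitted by REML
after a spectral decomposition of `K`: the restricted likelihood is
profiled over `delta = s2_e/s2_g` on a 100-point log grid spanning
[1e-5, 1e5] with golden-section refinement to a 1e-8 log-likelihood
tolerance; after rotation each evaluation is O(n). `delta` is then held
fixed across SNPs and each SNP tested by generalized least squares in the
rotated space (1-df Wald chi-square). Estimating the variance ratio once
per trait rather than per SNP is the standard spectral-LMM economy and is
accurate when single-SNP effects are a small fraction of trait variance.
This single-stage scan stands in for a three-step Bayesian sparse LMM +
LMM hybrid whose full description is not publicly available; it preserves
the mixed-model architecture, the GRM correction, and all downstream
thresholds.

### Multiple-testing thresholds

The genome-wide threshold is `alpha / M_e`, with the effective number of
independent tests `M_e` computed from eigenvalues of SNP correlation
matrices in non-overlapping 200-SNP within-chromosome blocks: each
eigenvalue contributes `1(lambda >= 1) + (lambda - floor(lambda))`. Fully
duplicated SNPs give exactly M/2; independent SNPs approach M. Reference
inputs of 657,030 and 307,349 effective tests reproduce the published
thresholds 7.61e-8 and 1.63e-7 to three significant figures. The
suggestive threshold is fixed at 1e-5. Two caveats are deliberate and
documented: the block size (200) is a pragmatic default, as the original
calculator's windowing is not described; and eigenvalue-based `M_e`
estimators are known to under-count the *tail*-effective number of tests
under intermediate LD, so family-wise control at `alpha/M_e` is
approximate rather than conservative (the package's null-calibration study
measures this directly).

### Stratified cohorts and the result union

When one cohort carries sub-population structure (registry "sections"),
the pipeline scans the full cohort and nested subsets (all sections;
the two largest; the largest alone) and takes the union of suggestive
SNPs across scans, each judged against its own thresholds, with provenance
recorded. This mirrors nested-cohort GWA as a sensitivity-maximizing
answer to stratification that the GRM alone may not fully absorb.

### Meta-analysis

Per-SNP summary statistics from the two cohorts are aligned on
(chromosome, position) with sign flips for swapped ref/alt coding;
irreconcilable allele pairs are dropped and counted; only SNPs present in
both cohorts are analyzed. The fixed-effects estimate is the
inverse-variance combination. The primary test is a likelihood-ratio test
that assumes heterogeneity only under the alternative:
`beta_i ~ N(mu, se_i^2 + tau2)` with `H0: mu = 0, tau2 = 0` against
`mu` free, `tau2 >= 0`. The alternative is maximized by profiling `mu`
analytically and searching `tau2` on a 200-point log grid (up to
10x the largest sampling variance plus the largest squared effect) with
vectorized golden-section refinement; the p-value uses the asymptotic
boundary mixture `0.5 chi2(1) + 0.5 chi2(2)`. At k = 2 studies this
mixture is *conservative* — Monte Carlo calibration (10,000 null
replicates) puts the 5%-level rejection rate near 0.026, because the
probability that the boundary parameter estimate is interior falls below
one half at small k. The package reports the asymptotic p-value unchanged
and documents the conservatism rather than tabulating small-k corrections.
DerSimonian–Laird tau-squared (floored at zero) and Cochran's Q are
reported descriptively alongside.

The meta genome-wide threshold divides `alpha` by the *larger* of the two
cohorts' effective test counts on the shared SNP panel (the more
conservative choice). A meta region is called by clustering suggestive
RE2 SNPs with the same 500 kb chaining used for cohort regions — without
the five-SNP minimum, since single-SNP meta regions are permitted — and is
an MA-ROI when at least one SNP lies strictly below the genome-wide
threshold.

### Regions, boundaries, tiers

Suggestive SNPs (p < 1e-5) are chained along each chromosome: a SNP joins
the open cluster when it is within 500 kb of the previous suggestive SNP.
A cluster is a region of interest (ROI) when it contains at least five
suggestive SNPs and at least one genome-wide-significant SNP.

Two boundary definitions are computed for every region. The *fixed-size*
boundary extends the SNP span 500 kb in each direction (clipped at
chromosome ends; unclipped width is exactly span + 1 Mb). The *LD-bound*
boundary starts from a 1 Mb window beyond the span, marks every window SNP
in-LD when its maximum composite r² (squared Pearson correlation of
unphased dosages) against *any* of the region's member SNPs exceeds 0.3,
takes the widest contiguous in-LD run intersecting the span (bp extent;
ties broken by SNP count, then 5'-most), and extends outward absorbing
in-LD SNPs until an in-LD-free stretch of at least 100 kb is certified on
each side; the boundary is the outermost in-LD SNP before each gap. If the
gap cannot be certified inside the window, the window grows by 1 Mb and the
procedure repeats; at chromosome ends the boundary clips with a warning.
Three definitional gaps in the published description were closed as
follows: LD is computed against all member SNPs (most inclusive reading;
a top-SNP-only variant would be a one-line change), "widest peak" is
measured in bp extent, and the boundary sits on the outermost in-LD SNP
rather than the gap midpoint.

Sharing between regions (different traits within a cohort, or the same
trait across cohorts) holds when one region's SNP span intersects the
other's boundary interval, in the chosen boundary mode; strict containment
is available as a toggle but almost never holds between unequal window
expansions. Tiers follow the prioritization tree: **high** when the region
overlaps an MA-ROI of its trait or is shared across traits with ROI
support on either side; **medium** when it is an ROI in at least one
cohort; **low** when shared across traits without any ROI support;
otherwise removed. A region qualifying for several categories takes the
highest. For the "low" category the absence of ROI support is required in
all cohorts, the stricter of the two possible readings. Counts of unique
regions merge within-cohort shared groups (union-find components).

### Annotation

Positional candidate genes are all protein-coding genes, pseudogenes and
RNA genes whose interval intersects the region interval by at least 1 bp
(adjacency is not overlap; genes straddling a boundary are biologically
relevant, so full containment is not required). Biotypes are classified
from GFF3 attributes/feature types by a fixed documented mapping. An
optional over-representation test against user-supplied GMT gene sets uses
the upper-tail hypergeometric probability with Benjamini–Hochberg
adjustment; no ontologies are bundled and no external services are
queried, because database-version-dependent enrichment results are
deliberately out of scope.

## The simulator

`sim_config()` / `simulate_cohorts()` generate a two-cohort study with the
statistical structure the analysis assumes:

* **Genomes.** `n_snps` SNPs (default 10,000) on `n_chroms` autosomes
  (default 5), exponential inter-SNP spacing with mean `snp_spacing_bp`
  (default 25 kb, giving ~500 kb LD blocks of `block_size_snps = 20`
  SNPs). Ancestral alt-allele frequencies are Uniform(0.05, 0.95).
* **LD.** Within a block, adjacent haplotype alleles are copied with
  probability `within_block_r` (default 0.9, adjacent dosage r² ≈ 0.65–0.8)
  and redrawn otherwise — first-order Markov LD, controllable and cheap;
  LD is exactly zero across block borders. This is deliberately not a
  coalescent: there is no recombination-rate variation, no allele-frequency
  /LD coupling, and no long-range admixture LD, so passing tests speak to
  the pipeline's logic under block LD, not to robustness against every
  real-data LD pathology.
* **Population structure.** Cohort frequencies drift from the ancestral
  pool by the Balding–Nichols model with `fst_between_cohorts` (default
  0.1, typical of horse breed divergence); cohort 1 is split into
  `n_sections = 3` sub-populations with a further
  `fst_between_sections = 0.03` drift, emulating registry-section
  stratification. Pairwise Hudson Fst between cohorts recovers the
  configured value.
* **Cohort-specific variation.** Each LD block is shared (default 80%) or
  private to one cohort; a causal variant with scope `cohort1_only` sits in
  a cohort-1-private block. This models breed-private segregating variation
  — a variant absent from one breed takes its local haplotype associations
  with it — and is what makes "private causal implies no meta-analysis
  signal" a property the pipeline can be tested against. Real array
  differences additionally interleave shared and platform-specific SNPs
  within LD blocks; that nuance is intentionally not modeled.
* **Traits.** Latent trait = causal dosage effects (additive per alt
  allele, no dominance) + sex effect (0.25 SD) + age slope (0.02/yr) +
  farm intercepts ~ N(0, 0.5) over ~30 farms per cohort + polygenic values
  with covariance `s2_g K` (s2_g = 1) + residual N(0, 1). Quantitative
  traits are stored on the inverse-transform scale (exponentiated, or
  shifted and squared) so the pipeline's canonical forward transform
  restores normality; the binary trait thresholds the liability at the
  `liability_threshold` quantile (default 0.8, 20% prevalence).
* **Determinism.** A fixed seed yields byte-identical output files.
  `sim_site_frequencies()` reproduces the frequency/layout draw so causal
  SNPs can be chosen (e.g. a common variant mid-chromosome) before the full
  simulation; effect-size defaults in the bundled studies (per-allele 1.0
  at MAF ≈ 0.5, residual variance 1) are chosen for testability — the
  original study reports no effect-size scale for real loci.

## Numerical choices and degenerate inputs

* REML and RE2 grid-plus-golden-section searches bracket the best grid
  point; eigenvalues are clamped at zero (GRMs are PSD up to rounding) and
  the effective-test formula rounds eigenvalues to 8 decimals before
  `floor()` so exact-integer eigenvalues (duplicated SNPs) do not fall on
  the wrong side.
* Zero-variance SNPs are skipped by the scan (logged), excluded from the
  GRM, and treated as their own test in `M_e`; zero-variance LD vectors are
  "not in LD".
* p-values are floored at the smallest positive double rather than
  reported as 0, and the summary-statistic reader rejects p outside (0, 1].
* Ties in the widest-LD-run selection break by SNP count, then 5' position,
  making boundaries deterministic; rerunning any stage with the same inputs
  is byte-identical.
* Monomorphic HWE input returns 1; an all-missing dosage column is a hard
  error for allele frequencies.

## Study-scale checks

The package ships two study-level functions used by its acceptance
machinery. `null_calibration_study()` runs 20 fully-null studies
(300 samples/cohort, 10,000 SNPs) and reports per-seed KS uniformity of
scan p-values, genome-wide hit counts, and high-tier region counts. The KS
test is computed on p-values thinned to one SNP per simulated LD block:
the KS null assumes independent draws, and block dependence inflates the
statistic without any miscalibration of the marginal p-values — the same
reason QQ/lambda checks in GWAS practice use LD-pruned SNPs.
`recovery_study()` plants a shared and a cohort-private common causal
variant (effect 1.0) in 20 studies and reports how often the shared one is
covered by an MA-ROI's LD-bound interval, and the private one yields a
medium-tier cohort-1 region with no meta-analysis region at its locus.
Problem sizes throughout (10,000 SNPs, 5 chromosomes, 300 per cohort, 20
seeds) are the package's chosen study scale for these checks.

## Known limitations

* The scan is single-stage; no sparse-effect (BSLMM-style) pre-selection,
  no per-SNP variance re-estimation, no conditional/stepwise splitting of
  multi-signal regions.
* X-chromosome genotypes are carried through but not dosage-compensated;
  how males should be coded is left open, as in the source methodology.
* Family-wise control at `alpha/M_e` is approximate under intermediate LD
  (see thresholds section); the null study quantifies the excess.
* The RE2 asymptotic p-value is conservative at k = 2; no small-k
  correction tables are applied.
* Enrichment analysis is a local hypergeometric over user-supplied sets
  only — no live ontology queries, by design.
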