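---
title: "Methods: two-sample MR with multiple-trait colocalization for cell-specific drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with multiple-trait colocalization for cell-specific drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmoloc)
```

## The problem

Circulating cytokines and their receptors coordinate inflammation across
many cell types, which makes it hard to tell *which* molecular trait, acting
*through which cell type*, drives an immune-mediated disease. Observational
associations between biomarker levels and disease are confounded and prone
to reverse causation. `mrmoloc` implements a two-stage genetic strategy:

1. **Two-sample Mendelian randomization (MR)** uses SNPs robustly associated
   with a circulating biomarker as unconfounded proxies to estimate the
   biomarker's causal effect on disease risk, with the instrument-exposure
   and instrument-outcome associations taken from separate cohorts.
2. **Multiple-trait Bayesian colocalization** then asks whether, at the
   locus of the gene encoding the biomarker, the cell-type-specific
   expression signal (eQTL), the circulating protein signal (pQTL) and the
   disease association are all driven by one shared causal variant. Running
   the colocalization once per cell type turns a locus-level answer into a
   cell-type-level one.

Everything operates on GWAS-style summary statistics: per-variant effect
estimates, standard errors, allele frequencies, p-values and sample sizes.

## Mendelian randomization

### Estimators

For a single harmonized variant $j$ with exposure association
$\hat\gamma_j$ and outcome association $\hat\Gamma_j$, the **Wald ratio** is

$$\hat\beta_j = \frac{\hat\Gamma_j}{\hat\gamma_j},$$

with first-order delta-method standard error
$\sigma_{Yj}/|\hat\gamma_j|$, where $\sigma_{Yj}$ is the outcome-side
standard error. A second-order correction propagating the exposure-side
uncertainty is available via `wald_ratio(..., second_order = TRUE)` but is
off by default, matching common two-sample practice.

With several independent instruments the **inverse-variance-weighted (IVW)**
estimate is the fixed-effect meta-analysis of per-instrument Wald ratios,

$$\hat\beta_{IVW}
  = \frac{\sum_j \hat\gamma_j^2\,\sigma_{Yj}^{-2}\,\hat\beta_j}
         {\sum_j \hat\gamma_j^2\,\sigma_{Yj}^{-2}},
  \qquad
  \mathrm{se} = \Big(\sum_j \hat\gamma_j^2 \sigma_{Yj}^{-2}\Big)^{-1/2}.$$

Only the outcome-side standard error enters the weights, so the estimate is
identical to the slope of a weighted least-squares regression of
$\hat\Gamma$ on $\hat\gamma$ through the origin with weights
$\sigma_{Yj}^{-2}$ — a property the test suite checks against an
independent `lm()` fit. A single-instrument IVW call collapses to the Wald
ratio exactly.

### Two analysis modes

- **Conservative**: one *cis* instrument per exposure — the
  genome-wide-significant variant ($p < 5\times10^{-8}$) within 1 Mb of the
  encoding gene with the smallest p-value after a minor-allele-frequency
  filter (MAF $\ge 0.05$); estimated by Wald ratio. Exposures with no
  eligible cis variant are reported as skipped with a reason rather than
  silently dropped.
- **Liberal**: all genome-wide-significant instruments, *cis* or *trans*,
  after greedy LD clumping at $r^2 < 0.001$; estimated by IVW. Exposures
  reduced to a single post-clump instrument are excluded from this mode
  with a reason.

Multiple testing is controlled by the Bonferroni rule
$\alpha / (\text{exposures} \times \text{outcomes})$, where the counts are
the exposures and outcomes *actually analyzed in that mode*, not the
nominal panel size.

### Sensitivity analyses

- **Leave-one-out** re-runs IVW excluding each instrument in turn
  (whenever at least three are available); a causal claim that hinges on
  one variant shows up as a single large excursion.
- **Steiger directionality** compares the variance the instruments explain
  in the exposure against the outcome. The default per-variant estimator is
  $r^2 = t^2/(t^2 + n - 2)$ with $t = \hat\beta/\mathrm{se}$, applied on
  the log-odds scale for binary traits; for quantitative traits with
  effects in phenotype-SD units the $2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$
  form is available. The test statistic is the Fisher-z contrast of the two
  correlations. The estimator choice is a genuine free parameter — summary
  statistics do not identify it uniquely — and the t-statistic form was
  chosen as the default because it needs no unit assumptions.
- **Reverse MR** re-runs the analysis with disease as the exposure:
  instruments are clumped from the disease GWAS and harmonized toward the
  biomarker. One design choice deserves emphasis: in any true
  genotype → biomarker → disease chain, a biomarker-causal variant that
  happens to reach genome-wide significance in the disease GWAS would
  enter the reverse analysis, and its reverse Wald z-statistic equals the
  biomarker GWAS z-statistic — the reverse test would "detect" reverse
  causation purely because the forward effect exists. `reverse_mr()`
  therefore applies Steiger filtering to candidate instruments by default,
  excluding variants that explain more variance in the biomarker than in
  the disease; this keeps the reverse estimate a test of disease-liability
  effects rather than a mirror of the forward path. The unfiltered
  analysis remains available (`steiger_filter = FALSE`). When no eligible
  instrument survives, an explicit `underpowered` result row is returned,
  never a crash: small biomarker GWAS make underpowered reverse tests the
  common case in practice.

### Harmonization, clumping and windows

Harmonization aligns outcome effects to the exposure's effect allele,
matching alleles directly, after swapping, or after strand
complementation; swapped matches negate the outcome beta and flip its
frequency. Palindromic variants (A/T, C/G) cannot be strand-resolved from
alleles, so they are aligned by allele-frequency concordance when
informative and dropped when the minor-allele frequency is within 0.08 of
0.5 in either study (a common two-sample MR convention; configurable).

Greedy LD clumping repeatedly takes the smallest-p remaining variant as an
index and removes everything with $r^2 > 0.001$ against it; ties on
p-value break lexicographically by variant id so the output is invariant
to input order. The LD matrix is user-supplied (or simulated) — no remote
reference panel is consulted.

The *cis* window is anchored at the whole gene body $\pm$ 1 Mb
(coordinates 1-based inclusive, both gene ends) — the more inclusive
reading of "within 1 Mb of the gene", since a TSS anchor is not determined
by summary data alone.

## Multiple-trait colocalization

For each trait at each variant, evidence of association is summarized by a
Wakefield approximate Bayes factor. With $V = \mathrm{se}^2$,
$W = \text{prior SD}^2$, $r = W/(V+W)$ and $z = \hat\beta/\mathrm{se}$:

$$\log \mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r.$$

Effect prior SDs default to 0.15 for quantitative traits (phenotype-SD
units) and 0.2 for binary traits (log-odds), the coloc-family convention;
both are configurable and the defaults were never tuned to data.

A **configuration** states which traits are associated in the region and
how the associated traits partition into groups sharing one causal variant;
for three traits (expression *a*, protein *b*, disease *c*) there are
exactly 15 configurations including the null. The regional Bayes factor of
a configuration sums, over all assignments of *distinct* variants to
groups, the product of the member traits' ABFs at the group's variant.
Distinct-group placements exclude shared variants exactly — regions here
are small enough for exact sums via inclusion–exclusion over the partition
lattice of the groups — rather than by the usual independence
approximation. The null configuration has log BF 0.

Posteriors combine the regional Bayes factors with per-variant prior
probabilities $p_1 = 10^{-4}$, $p_2 = 10^{-6}$, $p_3 = 10^{-7}$ for a
variant being causal for exactly one, two or three traits (a group of $s$
traits contributes a factor $p_s$). $\mathrm{PPA}_{abc}$, the posterior of
the configuration in which all three traits share one causal variant,
declares colocalization at $\ge 0.8$. Per trait, the variant with the
largest ABF is reported as that trait's best SNP.

The pipeline applies two published entry rules: a pair enters
colocalization only if its MR p-value is below 0.05 in either mode (the
smaller of the two is used), and an expression dataset is analyzed only if
it has at least one regional eQTL at $p < 10^{-4}$ (strict inequality).
Genes absent from a cell type's expression panel are reported
`not_expressed`, mirroring how genes silent in a cell type must be handled
in real panels.

### Numerical choices

All Bayes-factor arithmetic runs in log space with log-sum-exp (regional
sums over many variants overflow or underflow otherwise); the
inclusion–exclusion sum separates positive and negative terms and combines
them with a log-difference. p-values are computed from normal quantiles in
log space, so reported $\log_{10} p$ stays finite far below
double-precision underflow, and raw p-values are clamped to the smallest
positive double. A region with more sharing groups than variants has no
valid placement and receives log BF $-\infty$ (posterior zero); a region
with fewer than two variants is an error. Single-instrument IVW is
special-cased to the Wald ratio so the two are bit-identical.

## The synthetic-data generator

The generator stands in for the immune-cell eQTL, cytokine pQTL and
disease GWAS panels the framework was designed around, none of which ship
with the package. It emulates:

- **LD structure**: haplotypes are drawn by thresholding a latent AR(1)
  Gaussian field at each variant's allele-frequency quantile; genotypes
  are sums of two independent haplotypes, so LD decays geometrically with
  distance and is analytically controllable.
- **Two-sample design**: every trait is measured in its own independently
  drawn cohort.
- **Causal wiring**: each trait has its own causal variants; the
  designated outcome trait can additionally be driven by the exposure's
  genetic score scaled by a true causal slope (creating a real MR effect),
  or colocalization can be created mechanism-free by giving two traits the
  same causal variant. One causal variant per trait per region is the
  default, matching the single-causal-variant assumption of the
  colocalization model; multi-causal scenarios are possible but exist to
  probe robustness only.
- **Summary statistics as released**: marginal single-variant regressions
  (linear for quantitative traits; per-variant logistic regression for
  binary traits, effects on the log-odds scale, prevalence calibrated
  through the intercept), with p-values exactly consistent with
  $\hat\beta/\mathrm{se}$ under the normal approximation.

It deliberately does **not** emulate genome-wide polygenicity, imputation
uncertainty, sample overlap between cohorts, population stratification, or
allele-frequency differences between studies. Passing tests therefore
demonstrate the statistical machinery is correct and well calibrated under
the stated generative model — not that real datasets satisfy that model.

### Packaged study conditions

Three scenarios are fixed in code and used by the test suite and the
acceptance script:

- `demo_scenario()` — one 120-variant region (25 kb spacing, AR(1) 0.6):
  expression of the target gene in three cell types (n = 500 each, 0.8 SD
  effects), a circulating protein (n = 5000; cis variant v010 at 0.35 SD
  plus trans variants v060/v110 at 0.30 SD), and a binary disease
  (n = 25 000, prevalence 0.2) with two causal variants of its own outside
  the cis window and a true protein-on-liability effect of 0.5. Only the
  monocyte eQTL sits on the shared cis variant. The sizes mirror the data
  landscape the framework targets: small molecular-trait GWAS, larger
  disease GWAS, few-hundred-sample expression panels. The effect sizes
  place the mediated disease signal at the shared variant well clear of
  the colocalization decision boundary across simulation seeds; the
  protein-causal variants may consequently reach genome-wide significance
  in the disease GWAS, and the reverse analysis relies on its
  directionality filter to draw instruments from the disease's own loci.
- `mr_recovery_scenario()` — five independent instruments (0.3 SD,
  n = 5000) and a continuous outcome in a second cohort of 5000 with
  residual SD 3, so the exposure explains well under 1% of outcome
  variance. That is the regime the fixed-effect IVW targets: its standard
  error carries no exposure-side uncertainty, and when the mediated share
  of outcome variance grows the true sampling variance of each ratio
  inflates by $\sqrt{1 + \beta^2\sigma_x^2/\sigma_Y^2}$ and nominal
  coverage is lost by construction, not by implementation error.
- `coloc_scenario()` — a 24-variant region with expression/protein/disease
  traits (n = 5000 each) driven either by one shared variant or by three
  well-separated ones; used to measure colocalization discrimination.

Problem sizes throughout (200 replicates per slope for coverage, 100
replicates per arrangement for discrimination, regions of at most 8
variants for exhaustive Bayes-factor enumeration) were chosen as the
smallest sizes at which the binomial or numerical tolerances being checked
are meaningful.

## Known limitations

- Correlated-instrument IVW, MR-Egger, weighted-median and other
  pleiotropy-robust estimators are out of scope; the liberal mode assumes
  post-clump instruments are valid and independent.
- The colocalization model assumes at most one causal variant per trait
  per region; allelic heterogeneity can split evidence across
  configurations and depress $\mathrm{PPA}_{abc}$.
- Steiger-based directionality (both the standalone test and the reverse-MR
  instrument filter) inherits the approximations of summary-level $r^2$
  estimation, particularly for binary traits.
- Harmonization cannot rescue palindromic variants with near-0.5
  frequencies; they are dropped by design.
- The Bonferroni thresholds of the two MR modes, with the analyzed-count
  denominators, reproduce $6.17\times10^{-4}$ ($9\times9$ tests) and
  $6.94\times10^{-4}$ ($8\times9$ tests) — the values the acceptance
  script recomputes.
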