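---
title: "Gene-based association testing in pedigrees: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association testing in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedassoc)
```

## The problem

Sequencing studies of families must test whole genes — a gene is the
natural functional unit, and rare variants are individually almost
uninformative — against a binary phenotype, while the sampled
individuals are relatives. A population case–control statistic applied
to such data has the wrong null variance: kinship correlates genotypes
across individuals, so the statistic's nominal chi-square reference is
mis-scaled and p-values are wrong. `pedassoc` implements four gene-level
statistics that handle this by a single scalar correction shared across
variants and methods.

## The correction factor

Let $A$ be the case set ($n_A$ members), $U$ the control set ($n_U$),
and $\phi_{ij}$ the pedigree kinship coefficient. For any variant, the
covariance of two individuals' minor-allele dosages is proportional to
$2\phi_{ij}$ (with $2\phi_{ii} = 1 + f_i$, $f_i$ the inbreeding
coefficient). The variance of the case–control difference in mean
dosage is therefore inflated — or deflated — relative to the
independence variance by

$$
P_{corr} \;=\; \frac{\dfrac{1}{n_A^2}\sum_{i,j\in A} 2\phi_{ij}
 \;+\; \dfrac{1}{n_U^2}\sum_{i,j\in U} 2\phi_{ij}
 \;-\; \dfrac{2}{n_A n_U}\sum_{i\in A,\,j\in U} 2\phi_{ij}}
 {1/n_A + 1/n_U}.
$$

Dividing a statistic whose null distribution is driven by that
difference-of-means variance by $P_{corr}$ restores the chi-square
reference. The factor is 1 exactly when all cases and controls are
mutually unrelated and non-inbred, and does not depend on genotype, so
it is computed once per case/control partition and shared by all genes
and methods.

Two properties deserve emphasis:

* **The cross-group term matters.** When relatives are split between
  the case and control sets — the typical situation when a dichotomous
  trait segregates inside families — the positive covariance between
  the two group means *shrinks* the difference variance, and the exact
  ratio drops below 1. Omitting the cross term (the classical
  two-independent-samples form, available as
  `correction_factor(..., include_cross = FALSE)`) always gives a
  factor $\ge 1$ and makes the corrected tests severely conservative in
  split-family designs: in the package's own null study the type I
  error of the corrected $T^2$ collapses to essentially 0 at
  $\alpha = 0.05$ under the within-only form, while the exact ratio
  restores nominal calibration. The exact form is the default for this
  reason.
* **Inbreeding enters through the diagonal** ($1 + f_i$), computed
  exactly by the kinship recursion; looped pedigrees need no special
  handling.

Kinship itself is computed from the pedigree document only (the
recursive algorithm: founders unrelated, $\phi_{ij} =
\tfrac12(\phi_{i,\mathrm{father}(j)} + \phi_{i,\mathrm{mother}(j)})$
processing individuals parents-first). Estimating kinship from markers
is out of scope.

## The four statistics

All four consume the same per-gene matrix: individuals × variants,
dosages coded 0/1/2 for copies of the **sample minor allele** (columns
with sample frequency above ½ are flipped; exact ties keep the ALT
allele), monomorphic columns dropped, missing genotypes imputed to the
column mean so that group means and MAFs are unaffected.

**Generalized $T^2$ (`t2_family`).** With $d$ the case-minus-control
mean dosage vector and $S$ the pooled within-group covariance,
$T^2 = \frac{n_A n_U}{n}\, d' S^{+} d$, referred to
$\chi^2_{\mathrm{rank}(S)}$ after division by $P_{corr}$. $S^{+}$ is
the Moore–Penrose pseudo-inverse with singular values below $10^{-8}$
of the largest treated as zero; linkage disequilibrium makes
rank-deficient $S$ routine, and the degrees of freedom follow the
numerical rank. A zero difference with zero covariance yields statistic
0 with df clamped to 1.

**CMC (`cmc_family`).** Columns with MAF below `rare_maf` (default
0.01, the conventional "rare < 1%" cutoff) are replaced by one 0/1
indicator of carrying any rare minor allele, then the $T^2$ machinery
runs on the reduced matrix. With no rare columns the test *is* $T^2$.
A mean-imputed fractional dosage counts as carrying; this is the only
place the imputation rule is anything but neutral, and it affects only
individuals with missing rare-variant calls.

**FPCA (`fpca_family`).** Variant positions are rescaled to $[0,1]$;
each individual's dosage profile is fit by least squares on an order-4
B-spline basis with $\min(m, 10)$ functions (floored at 4, the order-4
minimum — for $m \le 4$ the fit interpolates); functional principal
components are extracted using the basis Gram matrix (computed exactly
by per-interval Gauss–Legendre quadrature) as the $L^2$ inner product;
the smallest $K$ components explaining `variance_explained` (default
0.85) of total variance are kept; and the statistic is
$\frac{n_A n_U}{n}\sum_k (\bar s_{A,k} - \bar s_{U,k})^2 /
\hat\lambda_k$ with $\hat\lambda_k$ the *pooled within-group* score
variance, so each term is a squared two-sample $z$ and the sum is
$\chi^2_K$ after the $P_{corr}$ division. Genes with fewer than 3
variants are skipped (classed condition `pedassoc_skip`; recorded as
`NA` in scans): three points cannot support a functional estimate of
the allele-count profile.

**Chi-square minimum (`chi_min_family`).** Each variant's 2×2
minor/major allele-count table (cases vs controls) gives a 1-df Pearson
chi-square without continuity correction; each statistic is divided by
$P_{corr}$; the gene's p-value is the *minimum* over variants with no
within-gene multiplicity adjustment. That omission is deliberate and
the point of including the method: the min-p screen is strongly
anticonservative, increasingly so for genes with more variants, and the
package's null study reproduces exactly that inflation. A Šidák-adjusted
variant sits behind `sidak = TRUE` but is not the default. The
allele-count (rather than genotypic 2×3) table is the minimal-df
reading of a per-variant chi-square.

## Scanning and evaluating

`scan_genome()` reads VCF (biallelic records; multi-allelics skipped
with a warning), BED4 gene regions (0-based half-open: a variant at
1-based position $p$ belongs to a region when $start < p \le end$),
a PLINK FAM pedigree and a `fid iid pheno` phenotype table; analyzes
the individuals present in all inputs with non-missing phenotype;
computes $P_{corr}$ once; and runs the four tests per gene in input
order, deterministically. Genes with no polymorphic variants are
dropped with a recorded reason. The Bonferroni gene threshold is the
family level divided by the number of genes *loaded* (configurable in
spirit via `glance()`/`bonferroni_threshold()` — the denominator
choice matters only when many genes fail the polymorphism filter).

`type1_error()` and `power_estimate()` pool gene × replicate pairs as
Bernoulli trials (a per-replicate-averaged variant sits behind
`pool = FALSE`), excluding skipped entries from numerator and
denominator — so FPCA's denominator can be smaller than the others'.
Binomial standard errors accompany every estimate.

## The simulator

The generator emulates the statistical structure the tests assume,
not any particular cohort:

* replicated template pedigrees (trio, nuclear with $k$ children,
  three-generation), structure fixed across replicates;
* a fixed gene map: by default 1000 genes, 5–20 variants each, 60%
  rare (founder MAF uniform on 0.001–0.01) and 40% common (uniform on
  0.05–0.5);
* gene dropping: founder haplotypes drawn per variant as independent
  Bernoulli(MAF) alleles — linkage equilibrium among founders — and
  one allele per parent transmitted per variant by a fair coin;
* a logistic liability phenotype: baseline prevalence 0.3
  (a hypertension-like trait), common causal variants acting per copy
  and rare causal variants per carrier, every effect centered at its
  founder-frequency expectation so the baseline prevalence is the
  disease probability at the mean genotype however many causal
  variants are configured;
* replicates redraw founders, transmissions and phenotypes under
  per-replicate RNG substreams derived from one seed by fixed offsets,
  so runs are byte-reproducible and replicates i.i.d.

The default study size — 300 nuclear families of four (1200
individuals) and 1000 genes — is the package's standing null
calibration condition; it gives 1000 gene-level Bernoulli trials per
replicate, i.e. a 3-standard-error band of about ±0.021 around a
nominal 0.05.

What the simulator deliberately does **not** model, and hence what
passing tests do not establish about real data: within-gene linkage
disequilibrium (founder haplotypes are in equilibrium; real LD changes
the effective degrees of freedom of all four tests), shared-environment
or polygenic phenotype components (the null here is exactly
exchangeable given genotype; a familial random effect would stress
$P_{corr}$ beyond what kinship captures), genotyping error and
missingness mechanisms, and ascertainment of families through affected
members.

## Numerical and design choices

* **Pseudo-inverse tolerance** $10^{-8}$ relative to the largest
  singular value; df = numerical rank, never below 1.
* **MAF** is computed from all analyzed individuals pooled, matching
  the "minor allele in the analyzed sample" orientation rule; a
  frequency tie at 0.5 counts the ALT allele, making orientation
  deterministic.
* **Missing genotypes** are mean-imputed per column — the covariance
  stays estimable without dropping individuals, and MAF is unchanged.
* **Chi_min correction side**: the per-variant *statistic* is divided
  by $P_{corr}$ before the p lookup (rather than adjusting p-values
  directly), keeping all four methods on the same
  statistic-over-$P_{corr}$ contract.
* **Small-sample behaviour of $T^2$**: the chi-square reference is
  asymptotic. At 60 individuals the asymptotic p-value tracks a
  $10^5$-permutation reference within about 0.03 absolute; the test
  suite asserts agreement within 0.05.
* **Power comparisons are scenario-conditional.** With purely common
  causal variants, CMC carries the same signal as $T^2$ in fewer
  degrees of freedom and is, if anything, slightly the more powerful —
  collapsing costs nothing when rare variants are null. The
  $T^2$-beats-CMC ordering emerges under within-gene allelic
  heterogeneity: the packaged causal scenario uses 30 causal genes
  (of 60) with common effects of log-OR 0.15 and rare effects of
  log-OR ±1.5, half protective, which the carrier collapse washes out
  while $T^2$ accumulates each variant's contribution. The test suite
  and the acceptance script state this as a property of that scenario,
  not a universal ranking.

## Known limitations

* Pedigree-document kinship only; no marker-based or X-linked kinship.
* Biallelic variants only; multi-allelic records are skipped, not split.
* No covariates, quantitative traits, dominance codings or weighted
  (kernel) burden tests.
* The FPCA basis and retained-variance defaults (order 4, ≤10 basis
  functions, 85%) are sensible conventions, all configurable; no
  claim of optimality is made.
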