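---
title: "Regional heritability mapping: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regherit)
```

## The model

`regherit` localizes genetic variance by splitting the additive genomic
effect of a quantitative trait into a *whole-genome* part and a *regional*
part tied to a small window of consecutive SNPs:

$$
y = \mathbf{1}\mu + Zu + Zw + e, \qquad
\mathrm{Var}(u) = G\sigma_u^2,\;
\mathrm{Var}(w) = Q\sigma_w^2,\;
\mathrm{Var}(e) = I\sigma_e^2 .
$$

Here $y$ holds one pseudo-phenotype per individual — in the dairy setting
these are de-regressed breeding values (DRPs) of sires for milk (MLK), fat
(FAT) and protein (PRT) yield — $G$ is the genomic relationship matrix
built from **all** SNPs, and $Q$ is the regional relationship matrix built
from the window's SNPs only. Fitting both components jointly asks whether
the window explains variance *beyond* what genome-wide relatedness already
explains, which is a different (and often more powerful) question than
single-SNP association.

### Kinship and the 0/0.5/1 coding

Genotypes are coded 0, 0.5 and 1 for rare-allele homozygotes,
heterozygotes and common-allele homozygotes. The identity-by-state kinship
between individuals $i$ and $j$ over $n$ SNPs is

$$
f_{ij} = \frac{1}{n}\sum_{k=1}^{n}
  \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)},
$$

with $p_k$ the major-allele frequency. Relationship matrices use
$2f_{ij}$ off the diagonal. For the diagonal we use $2f_{ii}$ from the
same formula: under this coding $\mathrm{Var}(g) = p(1-p)/2$, so
$\mathrm{E}[2f_{ii}] = 1 + F$, the conventional "one plus inbreeding"
diagonal, without importing an external inbreeding estimator. This keeps
the matrix a single self-consistent expression, testable against the
equivalent VanRaden-standardized 0/1/2 cross-product (an exact algebraic
identity, verified in the test suite).

Practical details that matter:

* **Allele frequencies are estimated once**, from the whole post-QC
  sample, and reused for every regional matrix. Per-window re-estimation
  would change the estimand from window to window.
* **Missing genotypes** are mean-imputed with $p_k$ inside the
  cross-product (`build_grm()`); the pairwise `kinship_pair()` helper uses
  complete cases instead, which is the right thing for a two-individual
  query but would not give a positive semi-definite matrix.
* **Monomorphic SNPs** cannot be standardized and are dropped from $n$.
* A small **ridge** (default `1e-6`) is added to each matrix diagonal so
  downstream REML never meets an exactly singular covariance. At the
  default size it changes variance components in the fourth decimal at
  most.

### Windows

Windows contain a fixed number of consecutive SNPs (100, 20 or 10 by
convention) and overlap by half: starts at ordinals $1, 1+s, 1+2s, \dots$
with shift $s = \text{size}/2$, never spanning chromosomes. When the
regular grid does not end exactly at a chromosome's last SNP, one
additional end-anchored window covering the final `size` SNPs is appended,
so every SNP belongs to at least one window; chromosomes shorter than the
window size contribute a single all-SNP window. On the 29-autosome post-QC
counts of the 50K bovine panel (40,646 SNPs, `bta_snp_counts()`) this
scheme places exactly 798 windows of size 100.

## REML, the boundary test, and thresholds

`reml_fit()` maximizes the restricted likelihood by average-information
(AI) updates with step-halving, falling back to an
expectation–maximization step whenever the AI system is ill-conditioned
or the proposed step does not increase the likelihood. Starting values put
half the phenotypic variance on the residual and split the rest equally.
Convergence requires a log-likelihood change below `1e-6` and a relative
parameter change below `1e-8`, with at most 200 iterations.

Variance components are constrained to the non-negative orthant: a
negative proposal is projected to zero, a component pinned at zero is
removed from the update, and it re-enters only if its boundary gradient
turns positive. This boundary handling is not a numerical nicety — it is
what makes the null distribution of the test statistic a *mixture*.

Because the null hypothesis $\sigma_w^2 = 0$ sits on the boundary of the
parameter space, the LRT $= -2\ln(L_0/L_1)$ is asymptotically distributed
as a 50:50 mixture of a point mass at zero and $\chi^2_1$. Accordingly:

* `mixture_pvalue()` returns 1 at LRT $= 0$ and
  $0.5\,\Pr(\chi^2_1 > \text{LRT})$ otherwise (raw statistics below
  `1e-8` are treated as the point mass);
* `lrt_threshold(alpha, N)` inverts the mixture with a Bonferroni
  correction over $N$ windows — with $N = 800/4000/8000$ it reproduces
  the conventional cutoffs 17.76/14.71, 20.83/17.76 and 22.16/19.08;
* `genomewide_neglog10p()` computes $-\log_{10}$ of the adjusted p-value
  entirely in log space, because a strong regional signal (e.g. LRT 210.9)
  has an adjusted p-value near $10^{-44}$, far below what a naive
  survival-function call can represent.

The Bonferroni $N$ defaults to the actual number of windows scanned;
`bonferroni_n` overrides it when reproducing analyses that used rounded
counts.

Two REML modes are available in the scan. The default re-estimates
$\sigma_u^2$ jointly in every window fit. `profile_u = TRUE` fixes it at
its null-fit value and optimizes only $(\sigma_w^2, \sigma_e^2)$, roughly
halving the work per window; on strong signals the two agree on the peak
window and differ modestly in LRT, which the test suite bounds. Joint
estimation is the default because fixing $\sigma_u^2$ biases the LRT when
a window carries appreciable variance.

## GRAMMAR single-SNP association

`run_grammar()` implements the two-stage residual association: fit the
whole-genome model once, take $\hat e = y - \mathbf{1}\hat\mu - \hat u$,
then regress $\hat e$ on each SNP's dosage by least squares with an
F-test on $(1, n_c - 2)$ degrees of freedom over that SNP's complete
cases. No GRAMMAR-gamma rescaling is applied, so test statistics are
mildly deflated and the procedure is conservative — the family-wise error
check in the test suite reflects that. Deflation is strongest when the
SNP panel is small relative to $n$, because the whole-genome BLUP can then
absorb most of an individual SNP's signal; with realistic panel sizes
(thousands of SNPs) the ranking agrees closely with a per-SNP
mixed-model score test (Spearman $\rho > 0.95$ in the suite).

## Effect correlations and genotype partitions

`effect_correlations()` takes per-trait fits at a common window and
correlates all whole-genome and regional BLUP vectors, with two-sided
p-values from the $t$ approximation on $n-2$ degrees of freedom — the
standard choice at these sample sizes. A BLUP vector with zero variance
(a regional component estimated on the boundary) produces `NA` entries
rather than zeros, so degenerate fits remain visible. This analysis is
what exposes antagonistic pleiotropy: a window whose allele raises fat
yield while lowering milk and protein yield shows a strongly negative
correlation between the FAT regional effect and the MLK/PRT regional
effects even while all whole-genome effects correlate positively.
`genotype_partition()` labels individuals by genotype class at a chosen
SNP (MM/Mm/mm/missing) and attaches regional effects for plotting;
per-class means are monotone in dosage when a single causal variant
drives the window.

Note one subtlety of interpreting whole-vs-regional correlations under
the null: conditioning on a boundary-escaping fit ($\hat\sigma_w^2 > 0$
on data with no regional signal) selects fits where $\hat u$ and
$\hat w$ partly co-fit the same noise, so the few defined correlations
skew positive rather than scattering symmetrically around zero. The
package reports them; it does not hide them behind zeros.

## The synthetic generator

No sire dataset is distributed with the package, so `sim_config()` /
`simulate_dataset()` generate data with the statistical structure the
analysis assumes:

* **Genotypes**: per-SNP minor allele frequencies uniform on a
  configurable range (default 0.05–0.5, comfortably inside the 1% QC
  cut), genotypes in Hardy–Weinberg proportions from two independent
  haplotypes, base-pair spacings of 20–80 kb (≈50 kb mean, as on a 50K
  array). Linkage equilibrium by default; an optional first-order
  parameter (`ld`) draws haplotype alleles from a Gaussian-copula AR(1)
  so the regional signal can spread over neighbouring SNPs as in real
  data. LD strength does not change any model-fitting contract, which is
  why equilibrium is the default.
* **Traits**: per-SNP effects multivariate normal across traits —
  correlation `polygenic_corr` (default 0.85, matching the strongly
  positive genetic correlations among milk yield traits) over all
  non-window SNPs, and `regional_corr` over the window SNPs, whose sign
  pattern encodes antagonism. Each trait's genetic-value vector is
  rescaled so its realized variance hits the target exactly; this removes
  one layer of Monte-Carlo noise from parameter-recovery studies without
  changing the covariance structure (scaling preserves correlations).
  Residuals are homoskedastic — sires evaluated from 50+ daughters have
  near-uniform DRP reliabilities, and no weighting is modelled.
* **Defaults** ("cattle-small"): 29 chromosomes scaled proportionally
  from the 50K panel to ≈2,000 SNPs, 1,000 individuals, variance
  magnitudes mirroring MLK/FAT/PRT DRPs (whole ≈ 5000/490/390, regional
  ≈ 240/43/6, residual ≈ 5000/500/400), a 20-SNP pleiotropic window at
  the start of chromosome 14, and 1% missing genotypes.

What the generator does **not** emulate: pedigree/half-sib structure,
selection across generations (antagonism is injected through
`regional_corr`, not evolved through negative linkage disequilibrium),
heteroskedastic DRP reliabilities, and multi-allelic variation. Passing
tests therefore demonstrate correctness of the estimators on data meeting
the model's assumptions, not robustness to every feature of field data.

## Verification strategy and problem sizes

The package's empirical claims are checked at sizes a single CPU handles
in minutes; these sizes are part of the package's own study design:

* **Null calibration**: 200 replicates at $n = 500$ (800 SNPs, one
  20-SNP test window, no regional signal). The fraction of LRT $= 0$ must
  fall in $0.5 \pm 0.08$ and the upper-quartile statistics must pass a
  Kolmogorov–Smirnov test against the conditional $\chi^2_1$ law at the
  1% level. The KS check deliberately targets the upper quartile: close
  to the boundary the asymptotic mixture is least accurate at moderate
  $n$, while threshold decisions live in the tail.
* **Ratio recovery**: 50 replicates at $n = 1000$ on the cattle-small
  genome with a FAT-like 8% regional ratio; the mean estimated
  $\sigma_w^2/(\sigma_u^2+\sigma_w^2)$ must be within 2 percentage
  points. This study pairs the estimator with a whole-genome matrix that
  *excludes* the window, so the generating ratio is exactly the estimand.
  With the scan's default $G$ (all SNPs, as the mapping model defines
  it), part of the window variance is absorbed by $G$ — approximately
  $\sigma_u^2 \, m_w/m_{\text{rest}}$ plus a finite-panel competition
  term, about one percentage point at these sizes — which is a property
  of the estimand, not an estimation error.
* **Sign recovery**: 20 replicates at $n = 800$ (≈1,000 SNPs, 20-SNP
  window) with regional correlations $(-0.9, +0.95, -0.9)$ against a
  $+0.85$ polygenic background and all-trait regional ratios near 8%; at
  least 90% of replicates must reproduce the full sign pattern (positive
  whole-genome block, FAT-antagonistic regional block). The ratios are
  set at the *detectable* scale: at a 1.5% ratio (the weakest trait in
  the motivating analysis) the regional component is not estimable at
  desk-scale $n$, and its correlations would be `NA` by design.
* **Oracle equivalence**: on $n \le 30$ instances, the restricted
  likelihood matches a direct projection-matrix evaluation and the BLUPs
  match an explicit mixed-model-equation solve, both to $10^{-6}$.

## Known limitations

* Univariate REML only: between-trait relationships are assessed by
  correlating univariate BLUPs, not by bivariate REML genetic
  correlations.
* The only fixed effect is the intercept; records map one-to-one to
  individuals.
* Bonferroni control over overlapping windows is conservative; no
  permutation or FDR alternatives are provided.
* GRAMMAR statistics are deflated (no gamma correction); use them for
  ranking and conservative significance statements.
* The exact-test HWE filter and all QC comparisons remove a marker only
  when it falls *strictly below* a threshold, so boundary cases are kept.
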