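---
title: "Mapping pleiotropic genes from multi-disease GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pleiotropic genes from multi-disease GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Common diseases co-occur in patients far more often than chance predicts,
and a large share of that comorbidity is genetic: pairs of diseases show
substantial genetic correlations estimated from GWAS summary statistics.
Genetic correlation, however, is a global summary — it says nothing about
*which* genes drive the sharing. `pleioscan` implements a pipeline that goes
from per-disease GWAS summary statistics to an explicit disease–gene
network: it (i) estimates all pairwise genetic correlations and extracts the
fully connected disease cluster, (ii) finds pleiotropic genes by three
complementary routes, and (iii) integrates the routes into a pleiotropy
table, a shared-gene disease network, and gene-set enrichment. A
synthetic-data module generates every input format with planted ground
truth, so the full pipeline is testable offline.

## Pipeline stages and their models

### Quality control

SNPs are retained when they are autosomal, have minor allele frequency
strictly above `1e-5`, and fall outside an excluded high-LD region
(an MHC-like segment; coordinates are 1-based inclusive). Diseases are
retained when they have strictly more than 1,000 cases. `qc_filter()` is
idempotent and order-preserving.

### Genetic correlations and the fully connected cluster

`estimate_rg()` implements cross-trait LD-score regression on z-scores:
for SNP $j$ with LD score $\ell_j$ (the sum of squared correlations with
the SNPs of its LD block),

$$E[z_{aj}^2] = 1 + h_a^2\,\ell_j,\qquad
  E[z_{aj} z_{bj}] = \rho_{g,ab}\, h_a h_b\,\ell_j + c_{ab},$$

where the free intercept $c_{ab}$ absorbs sample overlap. Slopes are fitted
with the customary two-pass weights $1/(\ell_j (1 + \hat h^2 \ell_j)^2)$
(cross-trait: the product of the two variance factors), which counter LD
redundancy and chi-square heteroskedasticity. SNPs with $z^2 > 80$ in
either trait are excluded, the usual guard against single outlier loci
dominating the slopes. $r_g$ is the ratio $\widehat{\mathrm{cov}} /
\sqrt{\hat h_a^2 \hat h_b^2}$; its standard error comes from a delete-one
jackknife over 20 contiguous SNP blocks and the p-value from a two-sided
normal approximation of $r_g/\mathrm{se}$. Non-positive heritability
estimates yield `NaN` with a reason code rather than an error.

The disease graph has an edge wherever $p \le 0.05$ (inclusive, two-sided;
the direction of the correlation is not restricted). The fully connected
cluster is a *maximum clique*, found exactly (`igraph::largest_cliques`);
among maximum cliques, ties are broken first by the larger sum of
$-\log_{10} p$ over clique edges and then lexicographically, which makes
the output deterministic and oracle-checkable.

### Gene-based route

For every protein-coding gene with at least two SNPs between its
transcription start and end (1-based inclusive; boundary SNPs included),
two summary-statistic tests run per disease:

* **SKAT-O.** With weights $w_j$ (beta-density of MAF with shape
  parameters `(1, 1)`, i.e. flat, kept configurable), the statistic family
  is $Q_\rho = (1-\rho)\sum w_j^2 z_j^2 + \rho\,(\sum w_j z_j)^2$ over the
  grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$. Under the
  null, $z \sim N(0, R)$ with $R$ the local LD matrix, each $Q_\rho$ is a
  mixture of 1-df chi-squares whose weights are the eigenvalues of the
  weighted LD kernel. The reported p-value is the minimum over the grid
  corrected by the one-dimensional integration of the omnibus null
  (the Lee et al. SKAT-O construction).
* **Principal-component test.** Eigendecompose $R$, keep the smallest $k$
  leading components whose cumulative eigenvalue share reaches 85 %, and
  test $\sum_{i\le k} (v_i^\top z)^2/\lambda_i \sim \chi^2_k$. The 85 %
  rule is interpreted as a share of the LD-matrix eigenvalue mass — the
  only quantity available from summary statistics.

The two p-values are combined by the equal-weight Cauchy combination
(`acat_combine()`), and a gene–disease pair is significant when the
combined p is strictly below $0.05/20{,}000 = 2.5\times10^{-6}$, the
Bonferroni correction for the approximate number of protein-coding genes.
Genes significant in at least two diseases are pleiotropic candidates.
Because neighbouring genes in strong LD can carry identical association
patterns without being separable from association data, genes within
500 kb (boundary-to-boundary) of each other on one chromosome with an
*identical* significant-disease set form a cluster; a member is excluded
when its external evidence score is below 0.3 for every disease shared by
the whole cluster (missing scores count as 0; singleton clusters pass).
Exact set equality was chosen over looser pattern matching for
reproducibility.

### Coding-SNP route

SNPs with $p < 5\times10^{-8}$ (strict) in at least two diseases are
selected; each one annotated as `stop_gained`, `missense` or `synonymous`
passes its disease set to the corresponding gene (consequence `other`
contributes nothing; a SNP coding in two overlapping genes contributes to
both). Disease sets are unioned per gene, and provenance (supporting SNPs
and consequences) is retained.

### Cross-trait subset meta-analysis route

Per SNP, traits with single-trait $p < 0.1$ enter an exhaustive search over
nonempty subsets $S$ with per-trait sign flips:

$$Z(S) = \frac{\left|\sum_{k\in S} s_k w_k z_k\right|}
             {\sqrt{\sum_{k\in S} w_k^2}},\qquad
  w_k \propto \sqrt{n_{\mathrm{eff},k}},$$

maximised over $(S, s)$; with signs free, the optimum aligns $s_k$ with
$\mathrm{sign}(z_k)$, so the search reduces to subsets of $\sum w_k |z_k|$.
If more than `max_traits` (default 10) traits pass the prefilter, the
smallest p-values are kept. The multiplicity of the search is adjusted by
Monte Carlo: a single null reference sample of the max-over-subsets
statistic (common random numbers, shared across SNPs; trait independence by
default, a trait-correlation matrix is accepted) replicates the prefilter,
conditions on at least one trait entering, and supplies the rank-based
p-value. A rank against $B \le 10^5$ draws cannot resolve p-values near
$5\times10^{-8}$, so beyond the upper Monte-Carlo quantile (50 exceedances)
the tail is extrapolated as $N_{\mathrm{eff}}\cdot 2\Phi(-t)$ with
$N_{\mathrm{eff}}$ calibrated on that same quantile — an effective number
of independent subset tests. The reported p never drops below the
unadjusted tail of the best subset. `n_sig_traits` counts the best-subset
traits with single-trait $p < 5\times10^{-8}$.

Independent loci then come from greedy clumping with PLINK-1.9 semantics
(`--clump-p1 5e-8 --clump-p2 1e-5 --clump-r2 0.1 --clump-kb 1000`),
followed by a merge of index SNPs within 500 kb (inclusive, leftmost pair
first, re-scanned to fixpoint). The merged index is chosen by a cascade:
both in the same gene → smaller p; p-values at least an order of magnitude
apart (ratio ≥ 10, strict) → smaller p; one inside a gene → that one;
more significant traits; smaller p; smaller position. Each final locus is
assigned the gene containing its index SNP (smallest span, then
lexicographic, when several overlap) or the nearest gene within the locus
bounds; loci with no overlapping gene are reported without a gene.

### Integration

The three gene→disease maps are unioned with per-pair method provenance;
genes with fewer than two diseases after the union are dropped. The disease
network connects two diseases whenever they share a gene (edge weight =
shared-gene count; isolated diseases are reported explicitly so the
connectivity claim is checkable). Genes are classified as within- or
cross-category from the disease metadata. Enrichment is a one-sided
hypergeometric upper tail per gene set against an explicit background (all
annotated genes by default — a reproducible substitute for web-service
defaults that cannot be recovered), with Benjamini–Hochberg adjustment and
significance at adjusted $p < 0.05$.

## The synthetic study

`sim_config()` defines the study the package is tested on. Defaults: six
binary diseases; three chromosomes with 50 independent LD blocks each
(20 SNPs per block, 2 kb spacing, blocks 1.2 Mb apart so clumping windows
never span blocks); first-order autoregressive LD within blocks with decay
spread evenly over $[0.4, 0.9]$ along each chromosome (LD scores then vary
from ~1.3 to ~9, the spread LD-score regression needs); 60 genes spread
evenly over blocks, each a centred run of 8 SNPs with 500 bp flanks, every
seventh gene non-coding; MAF uniform on $[0.01, 0.5]$ with a 2 % tail
below $10^{-5}$ to exercise the MAF filter; an excluded MHC-like region
covering one block of chromosome 2; case counts 4,000–20,000 of 100,000.

Summary statistics are simulated directly at the z-score level — all
downstream methods consume summary statistics only, so no genotypes are
needed. For a block with LD matrix $R$,

$$z_d = R(\lambda_d + \gamma_d) + \eta_d,$$

with $\lambda_d$ the planted per-SNP noncentrality (nonzero only inside
planted genes whose disease subset contains $d$; default four planted
genes on well-separated blocks with subsets of two to three diseases and
$\lambda = 3$, giving central z-means above 8 and single-SNP power well
above 0.99 at $5\times10^{-8}$), $\gamma_d$ a polygenic effect with
per-SNP standard deviation `poly_sd` and cross-disease correlation
`rg_target`, and $\eta$ LD-structured noise whose cross-disease
correlation defaults to `rg_target` (so the marginal correlation of null
z-scores equals the target genetic correlation; the overlap correlation is
exposed as a knob because real sample-overlap structure varies). Betas and
standard errors derive from allele frequency and the effective sample size
$4/(1/N_\mathrm{case} + 1/N_\mathrm{ctrl})$.

Two design choices deserve emphasis:

* **Polygenic effects live only on blocks without annotated genes.** A
  real genome dilutes the polygenic background over millions of SNPs, so
  per-gene polygenic noncentrality is negligible; compressing that
  background onto 3,000 SNPs would give individual genes genuine
  multi-disease signal and make a planted-truth false-discovery criterion
  meaningless. Restricting the background to intergenic blocks keeps the
  gene-test null exactly $N(0, R)$ while leaving the genetic correlation
  estimable — the attenuation from inactive blocks cancels between the
  genetic-covariance and heritability slopes, so $r_g$ is unbiased (which
  the tests confirm empirically).
* **`poly_sd = 1` is deliberately large.** It concentrates a genome-wide
  polygenic signal onto a desk-scale panel so that LD-score regression has
  power at 3,000 SNPs. Even so, per-edge power for detecting
  $r_g = 0.5$ at $p \le 0.05$ is only ≈ 0.5 at this scale, so the fully
  connected cluster is usually a strict subset of the six diseases —
  qualitatively the same outcome as a real multi-disease panel, where the
  fully connected cluster is a small fraction of all diseases analysed.

What the generator does **not** emulate: imputation quality, allele-flip
ambiguity, population stratification, X-linked variation, MAF-dependent LD,
and realistic gene length variation. Passing tests therefore demonstrate
the correctness and calibration of the pipeline's statistics under its
stated model, not robustness to those artefacts.

## Numerical choices

* Mixture-of-chi-square tails are computed by numerical inversion of the
  characteristic function (Imhof's formula). Generic adaptive quadrature on
  the infinite domain silently misconverges for these oscillatory
  integrands, so the implementation uses composite Simpson quadrature on a
  finite window (step resolving both the oscillation period $4\pi/q$ and
  the arctangent scale) plus an integration-by-parts tail correction;
  absolute error is ~$10^{-8}$ or better. Below $10^{-8}$ — the
  cancellation floor of the inversion — and above 0.9, the Liu
  moment-matching approximation takes over, mirroring the behaviour of
  Davies-based implementations.
* Near-singular LD matrices are ridge-regularised on the diagonal
  ($10^{-6}$, retried at $10^{-4}$); eigenvalues carrying less than
  $2\times10^{-4}$ of the largest are dropped from the SKAT-O kernels
  (near $\rho = 1$ the kernel is almost rank one and the discarded mass is
  negligible).
* $\rho = 1$ is evaluated as 0.999 in the omnibus machinery, the standard
  device to avoid the degenerate burden-only limit.
* Cauchy combination: p-values of exactly 1 are clipped to $1 - 10^{-15}$;
  inputs below $10^{-16}$ use the asymptotic tangent $1/(p\pi)$.
* In `merge_loci`, "within 500 kb" is inclusive (`<= 500000` bp between
  index positions) and "less than one order of magnitude" means
  $p_\mathrm{large}/p_\mathrm{small} < 10$, strict. Merging is
  leftmost-first and re-scanned to fixpoint, making chained merges
  deterministic.
* Ties: maximum-clique ties break by edge-strength sum then
  lexicographically; gene-assignment ties by smaller transcript span then
  lexicographic id; merge-cascade ties end at the smaller position.

## Problem sizes used by the test suite

The suite exercises the statistics at sizes chosen to make the checks
sharp while remaining desk-scale: null calibration of the combined gene
test pools 33 all-null studies (≈ 10,300 gene–disease tests, with binomial
confidence bounds evaluated at one gene per independent LD block);
single-SNP calibration uses one SNP per block for the same independence
reason; subset-meta uniformity uses 5,000 SNPs against a shared null of
50,000 draws; oracle equivalence runs 50 random graphs (12 nodes) against
$2^{12}$ subset enumeration, 100 random clumping regions, 200 randomized
merge instances, and exhaustive subset enumeration up to 12 traits;
genetic-correlation recovery uses 50 replicates of a 10,000-SNP,
two-disease study at true $r_g = 0.5$.

## Known limitations

* The subset meta-analysis assumes independent traits in its null sampler
  unless a correlation matrix is supplied; with strong sample overlap the
  Monte-Carlo null should be fed the overlap correlation.
* The tail extrapolation of the meta p-value is an effective-number
  approximation; p-values far below the Monte-Carlo resolution are
  order-of-magnitude estimates (their downstream use — seeding clumps at
  $5\times10^{-8}$ — only requires the threshold crossing to be reliable).
* LD-score regression at 3,000 SNPs has limited power; the package's own
  study design documents this rather than hiding it (see above).
* Enrichment results are methodologically comparable to, but not
  numerically reproducing, web-service enrichment runs, whose background
  universes are not recoverable.
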