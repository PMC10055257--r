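---
title: "Methods: cell-type-resolved pseudo-bulk eQTL mapping with multivariate shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved pseudo-bulk eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`scqtl` maps expression quantitative trait loci (eQTL) at cell-type
resolution from single-cell RNA-seq of a genotyped donor cohort. The
pipeline has six stages:

1. **Ingest and QC** — genotypes from VCF (or a dosage table) filtered on
   minor allele frequency, Hardy–Weinberg equilibrium and LD; cell-level
   counts filtered on mitochondrial read fraction; genes filtered on
   expression breadth and mean count.
2. **Pseudo-bulk aggregation** — per cell type, normalized log2 expression
   averaged to one value per donor per gene.
3. **Mixed-model cis scans** — per cell type and gene, an additive dose
   test and a genotype-by-disease interaction test under a
   two-random-effect linear mixed model.
4. **Joint shrinkage** — effect estimates across cell types are jointly
   modeled as a mixture of zero-centered multivariate normals, yielding
   shrunken posterior effects and local false sign rates (lfsr).
5. **Classification** — significance calling, top-eQTL selection,
   pairwise sharing, global/multi/unique labels, sign adjustment and
   profile pruning.
6. **Colocalization and enrichment** — approximate-Bayes-factor (ABF)
   colocalization against GWAS summary statistics, Fisher enrichment with
   TSS-distance-matched null variant sets, and a rank-sum differential
   expression test used for interaction-eGene overlap.

A synthetic-data module generates genotypes, kinship, cell-level counts
with planted effects, and GWAS summary statistics, so that every stage
can be validated against a known truth.

# The association model

For one gene in one cell type, let $y$ be the vector of per-donor
pseudo-bulk expression values. Expression is first transformed by the
rank-based inverse normal transform
$y^*_i = \Phi^{-1}\!\big((r_i - 0.5)/n\big)$ (average ranks for ties),
making the residual distribution robust to outliers and skew. The fitted
model is

$$ y^* = X\beta + g\,\beta_g + u + \varepsilon, \qquad
   u \sim \mathcal N(0,\ \sigma^2_K K + \sigma^2_w\,\mathrm{diag}(w)), \quad
   \varepsilon \sim \mathcal N(0, \sigma^2_e I), $$

where $g$ is the alt-allele dosage, $K$ the genomic relationship
(kinship) matrix estimated from the filtered SNPs
($K = X_{std}X_{std}^\top/m$), and $w_d = 1/\text{nCells}_d$ down-weights
donors whose pseudo-bulk mean was computed from few cells. Variance
components are estimated once per gene by REML under the null (no SNP)
and the resulting covariance **structure** is reused for every cis SNP of
that gene — the standard two-step approximation for mixed-model
association scans. On top of the fixed structure, the residual **scale**
is re-profiled per SNP and Wald tests use a t reference distribution with
the residual degrees of freedom. Two properties follow exactly:

* with $K = I$ and equal weights the scan reproduces OLS (coefficients,
  standard errors and p-values) to machine precision;
* dose recoding $g \to 2 - g$ flips the sign of $\hat\beta_g$ only.

For the **additive** scan, the top expression principal components
(default 20, capped at $n-2$) are regressed out of $y^*$ before the null
fit. For the **interaction** scan the PCs stay in the model as fixed
effects — disease status correlates with expression PCs, so removing
them beforehand would absorb part of the disease term. The interaction
design is $[1, PC_{1..k}, g, d, g\cdot d]$ with a Wald test on the
$g \cdot d$ coefficient; rank-deficient designs drop the offending PCs
with a warning.

**Inclusion rules.** Cell types enter the additive analysis with at least
40 donors having at least 5 cells (both configurable); donor–cell-type
pairs with fewer than 5 cells are dropped. The interaction analysis
additionally requires at least 10 diseased and 10 unaffected donors per
cell type (a 5/5 relaxation is exposed as a config override), and filters
variants to per-disease-group MAF above 5% — cohort-wide before testing,
and per cell type post hoc.

**cis window.** 1 Mb from the gene-body ends on either side, strand
agnostic (configurable, in bp). TSS distances are recorded signed and
strand-aware.

# Variant and cell filters

* MAF strictly > 0.05 and Hardy–Weinberg exact-test p strictly > 1e-6.
  The HWE test conditions on allele counts and sums the probabilities of
  heterozygote configurations no more probable than the observed one
  (optional mid-p correction).
* LD pruning in sliding windows of 250 variants advanced by 50, removing
  one of each pair with $r^2 > 0.9$ (the lower-MAF member; deterministic
  tie-break). This is the variant-count dialect of the usual
  `--indep-pairwise 250 50 0.9`.
* Cells with mitochondrial read fraction strictly above 20% are removed.
* Genes must be expressed (count > 0) in at least 10% of all post-QC
  cells, have mean count at least 0.1 across all cells, and not appear on
  exclusion lists (mitochondrial and ribosomal-protein gene symbols).
  Gene filters are computed study-wide, not per cell type, and applied
  after cell QC.

# Normalization

Per-cell size factors default to library sizes divided by their geometric
mean. When at least 100 cells are present, a pool-and-deconvolve
refinement over donor-level pools is applied: each donor pool's total
scale is estimated by a robust median ratio of the pooled profile to the
all-cell reference and redistributed over the pool's cells in proportion
to their library-size factors. Factors are rescaled to mean one and
expression is $\log_2(\text{count}/sf + 1)$. This follows the
pool-and-deconvolve idea of single-cell normalization; exact parity with
any particular implementation is not claimed, and the donor-level pooling
makes the result invariant to cell order. Note that the mean-one rescale
is global: doubling one cell's counts doubles its size factor relative to
the others, and count/size-factor ratios are preserved up to that single
global constant.

# Joint multivariate shrinkage

Per association $i$ (gene–variant pair), the vector of effect estimates
across $R$ cell types is modeled as

$$ \hat b_i \mid \beta_i \sim \mathcal N(\beta_i, S_i), \qquad
   \beta_i \sim \pi_0\,\delta_0 + \sum_{k,l} \pi_{k,l}\,
   \mathcal N(0,\ \omega_l U_k), $$

with $S_i$ diagonal (the squared per-cell-type standard errors; the EE
parameterization on the effect scale). Cell types missing an association
are dropped from that row's likelihood rather than imputed.

**Covariance components.** Canonical: identity, one singleton per cell
type, and the all-ones (equal effects) matrix. Data-driven: the top-5 PC
rank-1 patterns of the strong-set z-scores plus the rank-5
reconstruction, refined by an extreme-deconvolution EM that re-estimates
covariances accounting for the per-row measurement error (eigenvalue
clipping at 1e-8 keeps every component PSD; the EM objective is checked
to be non-decreasing). The strong set is chosen by running univariate
adaptive shrinkage per cell type and keeping rows with minimum lfsr
strictly below 0.1; when that set is very large it is capped (default
1000 rows, smallest lfsr first) to bound the ED cost.

**Scale grid.** $\sqrt2$-spaced standard deviations covering
$[\min(s)/10,\ 2\max|\hat b|]$, squared into variance scales; each $U_k$
is normalized to unit maximum diagonal so the grid carries the overall
scale.

**Weights.** Fitted by EM on a random subset (default 10,000
associations, seeded). The weights carry a null-biased Dirichlet prior
(10 pseudo-counts on the null component, 1 elsewhere). Without it the
null weight diffuses into near-zero-variance grid components that are
likelihood-indistinguishable from the point mass, and the lfsr loses its
conservative behavior on null data; the penalty restores the standard
conservative calibration. Convergence is declared at a relative objective
change below 1e-8 (cap 1,000 iterations), and the objective is asserted
to be non-decreasing.

**Posteriors.** Mixture-of-normals posteriors per association give the
posterior mean, posterior sd, and
$\text{lfsr} = \min\{P(\beta \le 0 \mid \hat b),\ P(\beta \ge 0 \mid \hat b)\}$
per cell type, with the null mass counted in both signs. The inner loops
(per-row component likelihoods and posterior moments) are implemented in
C++ (RcppArmadillo).

# Significance, sharing and classification

* An association qualifies if its minimum lfsr across cell types is
  $\le 0.05$; within qualifying rows, each cell type with lfsr $\le 0.1$
  is called significant (both thresholds inclusive).
* Per (gene, cell type), the **top eQTL** is the significant association
  with the smallest lfsr; ties break by larger absolute posterior effect,
  then lexicographic variant id. The top table is the union of selected
  gene–variant pairs.
* **Pairwise sharing** between two cell types: among top eQTL significant
  in both, the fraction with the same sign and magnitude ratio
  $\min/\max \ge 0.5$.
* **Classes**: significant in 1 cell type → `unique`; in at least
  $R - 2$ → `global` (the two-cell-type buffer absorbs low-powered cell
  types; a count of exactly $R-2$ is resolved to `global`); otherwise
  `multi`.
* **Sign adjustment**: if the majority sign among significant cell types
  is negative the profile is flipped; exact ties are left unchanged.
* **Pruning**: per gene, profiles are the centered absolute posterior
  effects with non-significant entries zeroed. One eQTL is kept as is;
  two are both kept iff their Euclidean distance exceeds 0.2, else the
  one significant in more cell types survives; three or more are kept
  entirely when all pairwise distances exceed the threshold, otherwise
  complete-linkage hierarchical clustering is cut at the $k \in 2..5$
  (capped at $m-1$) maximizing the mean silhouette width (ties to the
  smallest $k$), keeping per cluster the eQTL significant in the most
  cell types. Remaining ties resolve by lower mean lfsr, then variant id,
  so pruning is deterministic and idempotent.

# Colocalization and enrichment

Per SNP, the Wakefield log approximate Bayes factor is
$\tfrac12\log(1-r) + z^2 r/2$ with $r = \sigma_p^2/(\sigma_p^2 + se^2)$.
Effect priors: $\sigma_p = 0.15$ for quantitative traits (the eQTL side
uses mash posterior means and sds in place of nominal statistics) and
0.2 on the log-odds scale when a case-control GWAS is detected via a
finite `case_fraction`. Hypothesis posteriors PP0–PP4 combine per-SNP
ABFs by log-sum-exp with priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$; the engine agrees with brute-force enumeration of all
causal configurations to 1e-12 on small regions. Tests run only when at
least 100 shared variable SNPs remain after harmonization (match on id or
on chrom:pos with allele alignment; swapped alleles flip the GWAS beta;
palindromic A/T and C/G variants are dropped). A colocalization is
called at PP4 ≥ 0.6.

Enrichment uses the two-sided Fisher exact test on in/out-foreground by
in/out-hit tables, with Haldane-corrected odds ratios when a cell is
zero. The matched null set is drawn by rejection sampling: acceptance
probabilities proportional to the ratio of kernel density estimates of
the target and pool distributions of absolute TSS distances.
Sheather–Jones bandwidths are used because the rule-of-thumb default
oversmooths multimodal distance distributions and biases the accepted
sample. Differential expression between disease groups uses the
Mann–Whitney U statistic reported as AUC, exact enumeration for
$n_1+n_2 \le 12$ and a tie-corrected normal approximation otherwise,
with Benjamini–Hochberg adjustment and a DE call at adjusted p < 0.1.

# The synthetic cohort generator

The generator is a first-class module whose defaults emulate the target
study design: 116 donors with 58% carrying the disease label, several
cell types with unequal mean cells per donor (8–80) and whole-donor
dropout, cis-SNPs in LD blocks, and a minority of donors in close-kin
families.

* **Genotypes**: haplotypes follow a block-copying law — within a block
  (default 5 SNPs, constant allele frequency drawn from the configured
  MAF range) adjacent variants share a latent uniform with probability
  `ld_r`, so adjacent-dosage correlation equals `ld_r` in expectation
  (r² ≈ 0.81 at the 0.9 default). Families copy founder haplotypes with
  probability $\sqrt{\text{relatedness}}$, giving the expected kinship
  coefficient within families.
* **Counts**: per cell, negative binomial with mean
  $\exp(b_g + \beta_c\,g + \beta_d\,d + \beta_{gd}\,g\,d + u)$, gene-level
  dispersion, and a donor random effect $u \sim \mathcal N(0,
  \sigma_u^2 K)$ drawn **independently per cell type** — matching the
  per-cell-type mixed model that is fitted downstream. (A donor effect
  shared across cell types would induce cross-cell-type error
  correlations that the diagonal-error shrinkage model does not
  represent.)
* **Planted patterns**: `global` (equal effects in all cell types),
  `multi` (a random subset of about half), `unique` (one cell type),
  `sign_flip` (all cell types, half of each sign), and
  `interaction_only` ($\beta_c = 0$, $\beta_{gd} \ne 0$). Note that an
  interaction-only effect has a nonzero *marginal* additive slope of
  $\beta_{gd} \cdot \Pr(\text{disease})$ when groups are pooled; the
  group-specific slopes (≈ 0 in controls, ≈ $\beta_{gd}$ in cases) are
  the identifying signature.
* **GWAS summary statistics**: a fresh unrelated panel is drawn from the
  same LD law, a quantitative trait is generated from a chosen causal
  variant (`shared`, `distinct` — a different LD block — or `null`), and
  per-variant marginal OLS statistics are reported.
* **Not emulated**: transcriptome-wide co-expression, doublets, ambient
  RNA, batch effects, and realistic haplotype panels. Passing tests
  therefore demonstrate the statistical machinery under the model's own
  assumptions, not robustness to every artifact of real single-cell
  data.

Mitochondrial fractions are Beta-distributed per cell, independent of
genotype; they exist to exercise the QC filter.

# Validation design and problem sizes

The test suite validates each stage against independent oracles
(closed forms, enumeration, OLS/`lm`, exact rank-sum counts) and then
runs simulation-based checks at sizes chosen to keep the suite fast while
leaving clear statistical margins: null calibration on ~2,000 gene–SNP
tests at 100 donors; lfsr calibration on 5,000 associations × 6 cell
types from a known prior; classification recovery on 32 planted genes
(|β| = 1, 100 donors, 6 cell types, 50 cells/donor), evaluated on each
gene's primary (most-selected, post-pruning) top-eQTL; interaction
recovery at 150 donors; and a full pipeline run on a bundled-style
fixture of 30 donors × 200 genes × 6 cell types, executed twice and
compared checksum-for-checksum. Calibration simulations use unlinked
SNPs (block size 1) so that p-value uniformity can be assessed with
standard tests.

# Decisions on points the protocol leaves open

* The cis window is 1 Mb (the value such pipelines use); the window unit
  is bp and configurable.
* Expression PCs are computed on the inverse-normal-transformed matrix.
* The interaction donor rule defaults to 10/10, with the 5/5 relaxation
  as a config override.
* The kinship matrix is a genomic relationship matrix computed from the
  filtered SNPs.
* The shrinkage model uses the EE (effect-scale) parameterization, the
  automatic √2 grid, 50 ED iterations, and a fitting subset of 10,000
  with a fixed default seed (2023).
* Sharing and classification operate on posterior (shrunken) effects.
* "Centered" in pruning means subtracting each profile's own mean from
  its absolute effects.
* Coloc priors are the conventional $10^{-4}/10^{-4}/10^{-5}$; the mash
  posterior sd stands in for the standard error on the eQTL side.

# Limitations

* The EMMAX-style reuse of null variance components slightly misstates
  per-SNP uncertainty for very large effects; the per-SNP scale
  re-profiling mitigates but does not remove this.
* The shrinkage model assumes independent errors across cell types
  within an association; overlapping donors violate this mildly in real
  data and more strongly when donor effects are shared across cell
  types.
* The ED refinement is a fixed-iteration EM with PSD projection, not a
  full-convergence fit; component recovery is validated in the tests.
* Colocalization assumes a single causal variant per trait per region;
  multi-signal fine-mapping is out of scope.
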