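---
title: "Pathway effects from GWAS summary statistics: the model behind pathmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway effects from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmix)
```

## The problem

Single-SNP genome-wide association studies of highly polygenic traits
(body stature in cattle is the motivating case) yield hundreds of thousands
of small additive effect estimates, few of which pass genome-wide
significance on their own. `pathmix` aggregates that signal at the level of
functional gene sets: it asks which pathways, as a whole, carry more effect
than expected, while accounting for the fact that pathways share genes and
are therefore correlated units of analysis.

The inputs are ordinary artifacts of a completed GWAS: a table of per-SNP
effect estimates, a GMT file of gene sets, and gene coordinates (GFF3/BED)
or a precomputed SNP-to-gene table. No genotypes or phenotypes are needed.

## From SNPs to a gene-level response

SNPs are assigned to genes by position (chromosome match and
`start - flank_bp <= pos <= end + flank_bp`; `flank_bp = 0` by default,
strand ignored). When several SNPs land in one gene, only the strongest
association represents the gene, so each gene contributes a single
observation. "Strongest" is taken as the largest absolute effect estimate,
consistent with the response being absolute effects; selection by smallest
p-value is offered as an alternative (`criterion = "min_pvalue"`). Ties are
broken by smaller p-value, then lexicographic SNP ID, so the collapsed
table is invariant to input order.

The gene-level response is

$$y_g = |\hat\beta_{s(g)}|,$$

the absolute effect of gene $g$'s selected SNP. Genes that belong to no
supplied pathway are excluded by default — they cannot inform pathway
effects and would only perturb the general mean — with
`keep_unmapped = TRUE` preserving the alternative reading.

## The mixed linear model

Pathway effects are modelled jointly as correlated random effects:

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{Z}\mathbf{t} + \mathbf{e},
\qquad
\mathbf{t} \sim N(\mathbf{0}, \mathbf{V}\sigma_t^2),
\qquad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma_e^2),$$

where $\mathbf{Z}$ is the binary gene-by-pathway incidence matrix (a gene in
$k$ pathways has $k$ ones in its row) and $\mathbf{V}$ encodes pathway
similarity through the Jaccard coefficient

$$V_{ij} = J(i,j) = \frac{|A_i \cap A_j|}{|A_i \cup A_j|}$$

for gene sets $A_i, A_j$. The Jaccard coefficient is a positive
semidefinite kernel, so $\mathbf{V}$ is a valid covariance with unit
diagonal; the test suite verifies its smallest eigenvalue on random gene-set
families.

Variance components are treated as known rather than estimated: the total
variance is the unbiased sample variance of $\mathbf{y}$, split in a fixed
ratio

$$\sigma_t^2 = r\,\sigma_y^2, \qquad \sigma_e^2 = (1-r)\,\sigma_y^2,
\qquad r = 0.3 \text{ by default.}$$

The ratio has no deeper justification than being a moderate prior share of
signal, so it is exposed as the `ratio_t` argument rather than hard-coded.
$\sigma_y^2$ is computed from the gene-level response (the model's
observation vector) with the $n-1$ denominator. REML/ML estimation of the
components is deliberately out of scope.

## Solving: Henderson's mixed model equations

$\hat\mu$ (generalized least squares) and $\hat{\mathbf{t}}$ (BLUP) solve

$$\begin{bmatrix}
\mathbf{1}'\mathbf{R}^{-1}\mathbf{1} & \mathbf{1}'\mathbf{R}^{-1}\mathbf{Z}\\
\mathbf{Z}'\mathbf{R}^{-1}\mathbf{1} & \mathbf{Z}'\mathbf{R}^{-1}\mathbf{Z} + \mathbf{G}^{-1}
\end{bmatrix}
\begin{bmatrix}\hat\mu\\ \hat{\mathbf{t}}\end{bmatrix}
=
\begin{bmatrix}\mathbf{1}'\mathbf{R}^{-1}\mathbf{y}\\
\mathbf{Z}'\mathbf{R}^{-1}\mathbf{y}\end{bmatrix},
\qquad \mathbf{R} = \mathbf{I}\sigma_e^2,\; \mathbf{G} = \mathbf{V}\sigma_t^2.$$

With $p$ pathways the coefficient matrix is only $(p+1)\times(p+1)$ —
a few hundred rows in a realistic KEGG analysis — so it is factorised
directly by Cholesky; no iterative solver is warranted at this scale. The
solution is algebraically identical to the dense GLS/BLUP closed form
$\hat\mu = (\mathbf{1}'\Sigma^{-1}\mathbf{1})^{-1}\mathbf{1}'\Sigma^{-1}\mathbf{y}$,
$\hat{\mathbf{t}} = \mathbf{G}\mathbf{Z}'\Sigma^{-1}(\mathbf{y}-\mathbf{1}\hat\mu)$
with $\Sigma = \mathbf{Z}\mathbf{G}\mathbf{Z}' + \mathbf{R}$; the test suite
keeps the two routes within $10^{-8}$ relative error on hundreds of random
instances, and `scripts/acceptance.R` recomputes that agreement.

**Numerical choices.** Duplicate (or effectively identical) gene sets make
$\mathbf{V}$ exactly singular — real KEGG maps can share entire gene
complements — so `build_covariance()` flags off-diagonal Jaccard values of
1 with a warning, and `solve_mme()` retries once with a configurable ridge
(`jitter`, default $10^{-8}\mathbf{I}$) added to $\mathbf{V}$ when the
Cholesky factorisation fails, reporting the ridge in the fit diagnostics.
`jitter = 0` is strict mode: singularity becomes an error naming the
offending pathway pairs. The reciprocal condition estimate of the
coefficient matrix is returned with every fit.

Two structural identities are useful sanity checks and are enforced in the
tests: adding a constant to every $y_g$ shifts $\hat\mu$ by that constant
and leaves $\hat{\mathbf{t}}$ untouched, and with $\mathbf{V} = \mathbf{I}$,
$\mathbf{Z} = \mathbf{I}$ the BLUP reduces to proportional shrinkage
$\hat t_i = (\sigma_t^2/\sigma_y^2)(y_i - \hat\mu)$.

## Significance

Each predicted effect is tested one-sided, $H_0: t_i \le 0$ versus
$H_1: t_i > 0$, by the upper-tail probability of the prior null density:

$$p_i = 1 - \Phi\!\left(\hat t_i / \sigma_t\right).$$

Only positively loaded pathways can be significant; $\hat t_i = 0$ gives
$p = 0.5$ and negative predictions give $p > 0.5$ by construction. Note the
reference scale is the *prior* standard deviation $\sigma_t$, not the
prediction-error standard deviation of the BLUP. Because the BLUP is
shrunken, $\mathrm{sd}(\hat t_i) < \sigma_t$, and the test is conservative:
under a global null the frequency of $p \le \alpha$ falls well below
$\alpha$ (the calibration test demonstrates this at 500 simulated null
studies). This convention is retained deliberately — it is the package's
defined test — and is the main reason reported p-values should be read as
a ranking with a conservative guarantee rather than exact tail
probabilities. Raw p-values are reported by default (`adjust = "none"`),
with a significance flag at `alpha = 0.05` (comparison `<=`);
Benjamini–Hochberg adjustment is available with `adjust = "bh"`.

## The synthetic-data generator

`simulate_study()` generates studies from exactly the generative model the
estimator assumes — matched-model recovery, the correct acceptance surface
for the solver and test. It does **not** emulate a GWAS: there is no LD, no
allele-frequency structure, no genotype sampling, and no estimation noise
correlated across SNPs. Passing recovery and calibration checks on this
generator therefore validates the estimator and pipeline mechanics, not
robustness to the pathologies of real summary statistics.

Construction, given a `sim_config()`:

* gene sets of the configured sizes in which consecutive pathways share
  `round(overlap_fraction * size)` genes, giving the covariance a banded
  non-trivial structure (`overlap_fraction = 0.2` by default);
* true effects $\mathbf{t} \sim N(\mathbf{0}, \mathbf{V}\sigma_t^2)$, with
  a configurable fraction of pathways forced to exactly zero
  (`null_fraction`); residuals per gene; true response
  $y_g = \mu + (\mathbf{Z}\mathbf{t})_g + e_g$;
* each gene's designated top SNP carries $y_g$ as its effect magnitude with
  a random sign (the model consumes absolute values, so random signs also
  exercise the $|\cdot|$ transform); decoy SNPs get multipliers drawn from
  $U(0.05, 0.95)$, strictly smaller in magnitude, so collapsing provably
  recovers the designated SNP;
* genes laid out as non-overlapping 1-kb intervals with 500-bp gaps on one
  synthetic chromosome; a constant standard error of 0.1 and its two-sided
  normal p-value accompany each effect so both selection criteria work.

Defaults: `mu = 1`, `sigma_y2_target = 0.04`, `ratio_t = 0.3`,
`snps_per_gene = 3`. The mean sits five total-SDs above zero, so the true
response is essentially never negative and the absolute-value fold is
negligible — a deliberate choice, since the model's response is a
magnitude. Gene-set construction is seeded by `seed` and the effect draws
by `seed + 1`, making every emitted file byte-reproducible.

`recovery_report()` compares a fit with the generator's truth: Pearson and
Spearman correlation of $\hat{\mathbf{t}}$ with $\mathbf{t}$, RMSE, the
type-I error rate among true-null pathways and power among non-null ones
(either is `NA` when its class is empty, e.g. power under a global null).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
200 random instances (up to 30 genes, 8 pathways) for solver/closed-form
agreement; 100 random gene-set families for the kernel's eigenvalue bound;
500 all-null studies of 40 pathways x 25 genes for calibration; 50
replicates at 40 x 25 (and gene coverages 5/15/45) for recovery; and one
179-pathway, ~5,000-gene study — the scale of a real cattle KEGG analysis —
for the end-to-end pipeline. These sizes keep a full run in the low minutes
on a single core while leaving the statistical conclusions stable across
seeds.

## Design choices where the design was open

* **"Strongest effect" = largest $|\hat\beta|$.** Consistent with the
  response being absolute effects; `min_pvalue` is provided since either
  reading is defensible. Default tie-breaks make results platform-stable.
* **Union reading of the Jaccard denominator.** The total number of genes
  "involved in" two pathways is read as the union size — the standard
  Jaccard coefficient, which the similarity is named after. A
  sum-with-double-counting reading would halve overlapping similarities and
  is not what "Jaccard" denotes.
* **Annotation is local-file only.** SNP-to-gene and gene-to-pathway
  assignment run from GFF3/BED/TSV/GMT inputs, never from web services,
  whose versions drift and which make runs irreproducible offline.
* **A SNP in overlapping genes represents each of them.** Excluding it
  would discard signal; multiplicity is visible in the assignment table.
* **Per-dataset invocation.** One run analyses one summary-statistic table;
  there is no meta-analysis mode. Stage counts (SNPs read, assigned, genes
  collapsed, pathways retained/dropped) are logged and echoed into the run
  metadata, because silent input attrition is the classic source of
  irreproducible pathway counts.

## Limitations

* The p-values are conservative by construction (prior-SD reference); do
  not interpret them as exact tail probabilities.
* Fixed variance ratio: a badly chosen `ratio_t` misstates shrinkage.
  The location of the significance ranking is robust (it is monotone in
  $\hat t_i$), but the p-value scale is not.
* Positional SNP assignment ignores functional consequence and LD: a SNP
  tagging a distant causal variant is credited to the gene it sits in.
* Gene sets with identical gene complements cannot be distinguished by the
  model; they are flagged, regularised, and share their estimated effect.
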