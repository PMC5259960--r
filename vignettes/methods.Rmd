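---
title: "Gene-gene Eigen-Epistasis: model, inference and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-gene Eigen-Epistasis: model, inference and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies test markers one at a time, which leaves
epistasis — joint effects of loci that depart from the sum of their marginal
effects — largely invisible. Testing all SNP-by-SNP products is both
combinatorially and statistically hopeless at genome scale. `ggee` works at
the **gene** level instead: each gene contributes one group of main-effect
columns (its SNPs, additively coded \(X_{ij} \in \{1,2,3\}\)), and each
unordered gene pair \((r,s)\) contributes one group of interaction columns
\(Z^{rs}\). The model for a quantitative trait is

\[
y_i = X_i^T \beta + Z_i^T \gamma + \varepsilon_i,
\]

with a logistic variant for case-control labels. The scientific question —
*which gene pairs interact?* — becomes a grouped variable-selection problem.

## Building the interaction variables

Three constructions of \(Z^{rs}\) are implemented, all exposed through
`build_interaction_design()`:

* **Eigen-Epistasis (`ggee`).** Let \(W^{rs}\) hold all \(p_r p_s\)
  pairwise products \(X^r_{ij} X^s_{ik}\). The interaction variable is
  \(z = W u\) with \(u\) the unit vector maximizing
  \(\widehat{\mathrm{cov}}^2(Wu, y)\). Because the objective is
  \(u^T W^T y y^T W u\), the maximizer is the leading eigenvector of a
  rank-one matrix and has the closed form \(u = W^T y / \lVert W^T y\rVert\),
  costing \(O(n p_r p_s)\). One column per pair.
* **PCA products (`pca`).** The first \(q\) principal-component scores of
  each gene's standardized SNP block are multiplied pairwise, giving
  \(q^2\) columns per pair (one when \(q = 1\), the default). The phenotype
  plays no role in the construction.
* **PLS components (`pls`).** Two-block partial least squares of \(X^r\)
  against \(T = [\,y \mid X^s\,]\); the \(X^r\)-side scores (\(q\) columns)
  represent the pair.

Numerical conventions worth knowing:

* For `ggee`, the columns of \(W\) and the phenotype are **centered** before
  forming \(W^T y\), so the maximized quantity is a literal sample
  covariance; uncentered cross products are confounded by allele
  frequencies. The uncentered variant is available via
  `eigen_epistasis(..., center = FALSE)`.
* Eigenvectors and singular vectors are sign-ambiguous. Signs are fixed so
  that \(\mathrm{cov}(z, y) \ge 0\) (`ggee`) or the largest-magnitude
  loading is positive (`pca`, `pls`), making results reproducible.
* With several PLS components, whether only \(X^r\) or also \(T\) is
  deflated between components is not canonical; this implementation
  deflates both blocks on the preceding score. The default \(q = 1\)
  sidesteps the ambiguity.
* All interaction columns (and all SNP columns) are standardized before
  penalized fitting, so that penalty weights compare group norms on a
  common scale. Pairs whose construction is degenerate (e.g. a phenotype
  orthogonal to every product column) are dropped with a warning.

## Estimation: weighted group lasso

Coefficients are estimated by the grouped penalty

\[
\tfrac12\lVert y - X\beta - Z\gamma\rVert^2
 + \lambda\Big[\textstyle\sum_g w_g\lVert\beta^g\rVert_2
 + \sum_{rs} w_{rs}\lVert\gamma^{rs}\rVert_2\Big],
\]

solved by block coordinate descent with *exact* block updates: each block
minimization reduces, in the eigenbasis of the block Gram matrix, to a
monotone scalar secular equation solved by bisection. Karush-Kuhn-Tucker
conditions are checkable on any returned solution (`kkt_check()`), and the
objective trace is recorded. \(\lambda\) is chosen by k-fold
cross-validation (default `k = 5`) over 50 log-spaced values from
\(\lambda_{max}\) (the smallest penalty zeroing every group, available in
closed form from the KKT conditions) down to \(10^{-3}\lambda_{max}\).

**Penalty weights.** Main-effect groups carry the standard weight
\(\sqrt{p_g}\). For interaction groups the displayed objective of the
source method reads \(\sqrt{p_r p_s}\), the dimension of the *unreduced*
product coefficient vector; applied to the reduced constructions (one
column for `ggee`) this penalizes interactions far harder
than a like-sized main group, and in simulation the causal pair is then
usually eliminated at the screening stage — at odds with the method's
reported behavior. The default is
therefore the standard group-lasso convention, weight = square root of the
**actual** column count of the built group; the literal reading remains
available via `grouped_design(..., interaction_weights = "nominal")`.

**Solver tolerances.** Cross-validation path fits use a loose tolerance
(`1e-4` on the maximum coefficient change, at most 300 sweeps); on test
instances the selected \(\lambda\) and selected groups are identical to
`1e-7` runs while being an order of magnitude faster. Final fits use
`1e-8`.

## Inference: screen and clean

`screen_and_clean()` performs two-stage selective inference:

1. **Screen.** On a random half of the individuals, fit the group lasso at
   the CV-selected \(\lambda\); groups with nonzero blocks are candidates.
2. **Clean.** On the other half, fit a ridge regression restricted to the
   candidate groups, with each block's quadratic penalty scaled by the
   group weight (ridge strength chosen by CV on that half). The statistic
   for group \(g\) is \(\lVert\hat\theta_g\rVert_2^2\).

The permutation null (default `perm = "group"`) permutes the **rows of the
tested group's columns only** and refits the ridge — efficiently, via the
Schur complement against the unchanged blocks, so B permutations cost
\(O(B\, n\, k_u k_g)\). This breaks the group's association with both the
response and the other candidates while preserving their joint fit: each
group is tested *conditionally on the others*. The alternative
`perm = "phenotype"` permutes the cleaning-half response, testing every
group against the global null; with correlated candidates the observed
statistic is computed amid competing signal while the null is computed
under none, which makes that scheme markedly conservative for
correlated candidates. Raw p-values are
\((1 + \#\{S_b \ge S\})/(B+1)\) — so \(1/(B+1)\) is the attainable floor —
and Benjamini-Hochberg adjustment across candidates controls the false
discovery rate; "significant" means adjusted p below `alpha` (default
0.05, `B = 999` for single analyses).

To avoid selection leakage, the default pipeline (`epistasis_scan(...,
strict = TRUE)`) draws the half-split *first* and estimates every
phenotype-dependent ingredient of the interaction construction
(Eigen-Epistasis \(u\), PLS weights, all centering/scaling statistics) on
the screening half only; the cleaning half's phenotype never influences
variable construction. `strict = FALSE` builds variables once on the full
data, as some pipelines do.

For binomial designs the screening stage maximizes the penalized logistic
likelihood (IRLS around the same solver); the cleaning ridge is fitted to
the centered 0/1 labels by least squares, which keeps the permutation test
exact under its null.

## Simulation design

`simulate_genotypes()` draws latent rows from a p-variate normal with
block-diagonal equicorrelation (within-gene \(\rho = 0.8\) by default,
zero across genes — a stylized LD structure) and discretizes each column
at standard-normal quantiles so genotype classes follow Hardy-Weinberg
proportions for that column's MAF: minor homozygote (coded 3) with
probability \(p^2\), heterozygote \(2p(1-p)\), major homozygote
\((1-p)^2\). Non-causal MAFs are uniform on \([0.05, 0.5]\); causal SNPs
get MAF 0.2. The published description of the discretization thresholds is
internally inconsistent; the implemented rule is the unique monotone
assignment consistent with the stated Hardy-Weinberg intent. Note the
direction of the coding matters downstream: pairwise products are *not*
invariant under relabeling \(1 \leftrightarrow 3\), and only the
minor-homozygote-is-3 direction reproduces the published variance
decomposition for the same-genes layout (the acceptance suite checks
this).

`simulate_phenotype()` builds the trait from standardized unit-variance
components — per causal gene, the standardized sum of its two causal SNPs
(the first two columns of the block; positions are exchangeable under the
block model); per causal pair, either the standardized sum of all causal
SNP products (`wang` trait model) or the standardized product of the two
genes' first principal components (`pca` trait model) — each weighted by a
common coefficient (default 2), intercept zero. Residuals are Gaussian
with variance chosen so the expected coefficient of determination equals
the target:

\[
\sigma^2 = \frac{(R^2 - 1)\sum_i (Q_i - \bar Q)^2}{R^2(2 - n)},
\]

where \(Q\) is the noiseless signal; the mean in the sum is the *signal*
mean, since the derivation eliminates the noise terms in expectation
before any noise is drawn. Empirically the realized \(R^2\) tracks the
target within ±0.03 at n = 600. The effect layouts (which genes carry
main effects, which pair interacts) are named presets A-F, OME (main
effects only) and NE (global null) in `sim_setting()`; the layouts pair
the same-genes and different-genes cases with the two trait models. For
the null layout the trait is standard normal noise and the target
\(R^2\) is ignored (there is no signal to calibrate).

`variance_decomposition()` reports \(p_I = 100\,R^2_I/R^2_T\) and
\(p_M = 100\,R^2_M/R^2_T\) from intercept-included OLS fits of the trait
on the true interaction components, the true main components, and both.
The two shares need not sum to 100: in the same-genes Wang layout the
product component is nearly collinear with the main sums and both shares
exceed 90.

What the generator does *not* emulate: realistic MAF spectra and LD decay,
linkage between genes, haplotype structure, or case-control ascertainment.
A green simulation test therefore establishes correctness of the
statistical machinery under the stated stylized world, not performance on
real genotypes. `simulate_genotypes_surrogate()` additionally draws
skewed gene sizes (geometric, median 2 by default, truncated at 1119) to
mimic the shape of real annotation-derived gene panels; it is labeled a
surrogate and is not a reproduction of any real panel.

## Study driver and reproducibility

`run_setting()` executes the replicate loop: simulate, build, screen,
clean, record which of the \(G + G(G-1)/2\) variables were significant
plus the replicate's \((p_I, p_M)\). Power for a causal pair is the
proportion of replicates in which it is declared significant after FDR
adjustment. One master seed deterministically derives per-replicate seeds
(`derive_seeds()`), so any replicate is reproducible in isolation and the
whole study is byte-reproducible. Study-scale runs default to `B = 199`
permutations; published-scale runs use 1000 replicates, and the package's
own checks use 40-200 replicates with correspondingly widened Monte-Carlo
tolerances.

## Known limitations

* The conditional permutation scheme tests each candidate group given the
  others; with heavily collinear candidates (same-genes layouts) main and
  interaction groups can share credit, and the confusion patterns the
  source literature describes (false interactions between main-effect
  genes, false mains on interacting genes) appear here too.
* Gene pairs are limited by memory to \(n \times p_r p_s\) product
  matrices; very large genes make `ggee` construction expensive.
* No exact post-selection theory beyond the permutation scheme; no
  confidence intervals for coefficients.
* Binomial-family cleaning uses least-squares on centered labels rather
  than a logistic ridge.
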