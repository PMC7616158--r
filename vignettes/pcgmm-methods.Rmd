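---
title: "Robust multivariable cis-Mendelian randomization with principal-component GMM"
author: "pcgmm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multivariable cis-Mendelian randomization with principal-component GMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgmm)
```

## The problem

A single gene region — typically the gene encoding a drug target and its
flanks — often contains several distinct causal variants with different
patterns of association across traits ("phenotypic heterogeneity"). When
those traits are candidate mediators of the drug's effect on a disease
outcome, multivariable Mendelian randomization over the region's variants
can, in principle, separate the causal contributions of the individual
traits and so illuminate the mechanism of action.

Two statistical obstacles stand in the way:

1. **Dense LD.** Variants in one region are strongly correlated, and the
   regional correlation matrix is frequently near-singular (real regions
   contain sets of variants in essentially perfect LD). Analyses that invert
   this matrix directly on the variant scale are numerically unstable.
2. **Overdispersion heterogeneity.** Some variants affect the outcome
   directly, not through the modeled risk factors. On top of the sampling
   noise, this adds excess dispersion to the variant–outcome associations.
   Ignoring it leaves point estimates consistent but makes confidence
   intervals too narrow, inflating type I error badly.

`pcgmm` addresses both: dimension reduction onto the leading principal
components of a weighted genetic correlation matrix, and
continuously-updating GMM (CUE-GMM) estimation with an overdispersion
parameter that corrects the standard errors.

## The model

Inputs are marginal (univariable) summary associations of each of $J$
variants with $K$ risk factors ($\hat\beta_X$, a $J \times K$ matrix with
standard errors) and with one outcome ($\hat\beta_Y$, length $J$), a $J
\times J$ signed LD correlation matrix $\rho$ estimated in a reference
panel, and a $K \times K$ risk-factor correlation matrix used to fill in
cross-trait sampling covariances (zero off-diagonals when trait pairs come
from non-overlapping samples or their correlation is unknown).

### PC transform

The weighted genetic correlation matrix is
$\Psi_{ij} = \rho_{ij}\, w_i w_j$ with weights
$w_j = \sum_k |\hat\beta_{X,jk}| / \operatorname{se}(\hat\beta_{Y,j})$,
so that components align with trait-relevant variation rather than with LD
structure alone. The weight aggregates the risk-factor association
strengths and the outcome precision; this choice is one of several
reasonable ones and is kept configurable (`weights = "none"` uses the raw
LD matrix).

Writing $\Lambda$ for the first $p$ eigenvectors of $\Psi$ — the smallest
$p$ whose eigenvalues cover a fraction `variance_threshold` of the total
positive spectrum — the multivariable regression coefficients of each
trait on the $p$ principal components are, with $S = \Lambda'\rho\Lambda$,

$$ b_Y = S^{-1}\Lambda'\hat\beta_Y, \qquad
   b_{X k} = S^{-1}\Lambda'\hat\beta_{X k}. $$

Their sampling covariance follows from the standard marginal-coefficient
covariance $D\rho D$ (with $D$ the diagonal of standard errors) by the
sandwich rule, e.g.
$\Omega_{YY} = S^{-1}\Lambda' D_Y \rho D_Y \Lambda S^{-1}$, and cross-trait
blocks are scaled by the supplied trait correlation. The correctness of
these variance formulas is verified empirically in the test suite: with
fixed loadings, the model covariance of $b_Y$ matches the sampling
covariance observed across simulation replicates to within Monte-Carlo
error.

### CUE-GMM estimation and the overdispersion parameter

The moment vector is $g(\theta) = b_Y - b_X\theta$ and the criterion

$$ Q(\theta, \kappa^2) \;=\; g(\theta)'\,
   \Omega(\theta, \kappa^2)^{-1}\, g(\theta), \qquad
   \Omega(\theta, \kappa^2) = \Omega_{YY}
   + \textstyle\sum_{k,l}\theta_k\theta_l\,\Omega_{XX}^{(k,l)}
   + \kappa^2 M, $$

re-evaluated at every candidate $\theta$ (continuous updating), which is
known to be less sensitive to weak instruments than two-step GMM. Direct
variant effects $\alpha_j$ with variance $\kappa^2$ enter the marginal
outcome associations as $\rho\alpha$, so their exact image on the PC scale
is $M = S^{-1}(\Lambda'\rho^2\Lambda)S^{-1}$; this is the default
(`overdispersion = "ld"`). The alternative `"gram"` structure
$M = S^{-1}$ corresponds to excess dispersion placed directly on the
marginal associations, and is retained as a sensitivity option. The choice
of the exact LD image is validated by the calibration simulations: the
robust Wald test of a null effect holds its nominal 5% level under strong
overdispersion.

The **unrobust** fit minimizes $Q(\theta, 0)$; its minimized value is the
overidentification (heterogeneity) statistic, $\chi^2_{p-K}$ under a
correctly specified model, and a rejection flags unexplained heterogeneity
(possible pleiotropy). The **robust** fit alternates minimization over
$\theta$ with a method-of-moments update of $\kappa^2$: the root of
$Q(\hat\theta, \kappa^2) = p - K$, found by bisection ($Q$ is monotone
non-increasing in $\kappa^2$ because $\Omega$ grows in the Loewner order),
floored at zero. Matching the objective to its degrees of freedom is
natural here because overdispersion affects inference rather than
consistency — the correction widens intervals without recentering
estimates. The variance of $\hat\theta$ uses the plug-in $\hat\kappa^2$
(the extra uncertainty from estimating $\kappa^2$ is not propagated); the
simulations show the resulting intervals are calibrated at the sample
sizes studied.

Standard errors default to the curvature of $Q/2$ at the optimum
(numerical Hessian), falling back to the Fisher-type
$(b_X'\Omega^{-1}b_X)^{-1}$ form when the numerical Hessian is not
positive definite; `se_method = "fisher"` selects the latter directly.

### Conditional F-statistics

Phenotypic heterogeneity for risk factor $k$ is tested against the rank
reduction in which its PC-scale associations are a linear combination of
the other factors': the statistic is the variance-standardized quadratic
form of $b_{Xk} - b_{X,-k}\delta$, divided by its degrees of freedom
$p - K + 1$, and compared (times the degrees of freedom) to the
$\chi^2_{p-K+1}$ quantile. The combination $\delta$ solves the GLS
estimating equations with the weight matrix re-evaluated continuously in
$\delta$. One design point deserves emphasis: *fully minimizing* the
weighted form (including its weight-derivative term) yields a statistic
that is invariant to which factor is singled out — a symmetric rank
statistic — because the criterion is scale-invariant along rays through
the coefficient vector. The estimating-equation solution deliberately
avoids that degeneracy and preserves the per-factor reading: at
$\xi = 0$ in the simulation design (factors 2 and 3 sharing instruments),
$F_{1|-1}$ stays large while $F_{2|-2}$ and $F_{3|-3}$ sit at their null
level. The degrees of freedom $p - K + 1$ (moments minus freely fitted
combination coefficients) are validated by the size simulation at
$\xi = 0$. Conditional F below 10 triggers the conventional
weak-instrument caution; below 1, the factor has essentially no unique
instrument signal. These are plain $\chi^2$ critical values, not
weak-instrument-adjusted ones.

### Colocalization and model averaging

Colocalization runs on the marginal (untransformed) associations of two
traits under the classical one-causal-variant-per-trait assumption:
per-variant Wakefield log approximate Bayes factors
$\tfrac12[\log(1-r) + r z^2]$, $r = \sigma_p^2/(\sigma_p^2 +
\operatorname{se}^2)$, aggregated over the $H_1$–$H_4$ configurations by
log-sum-exp with priors $(p_1, p_2, p_{12}) = (10^{-4}, 10^{-4}, 10^{-5})$
by default, plus a sensitivity grid over $p_{12}$. Effect-size prior
standard deviations default to 0.15 (quantitative traits); 0.2 is the
usual choice for log odds ratios and both are exposed as arguments since
the appropriate value depends on the trait scale.

Model averaging over risk-factor subsets applies to the PC-transformed
coefficients: each non-empty subset $s$ is scored by the closed-form
Gaussian evidence of $b_Y \sim N(b_{X,s}\theta_s,\ \Omega_{YY})$ with
independent effect priors $\theta_s \sim N(0, \sigma_{\text{prior}}^2 I)$
($\sigma_{\text{prior}} = 0.5$ on the standardized PC scale by default),
times an independent-inclusion prior $p^{|s|}(1-p)^{K-|s|}$ with
$p = 0.1$ (a prior expectation of about one causal factor in ten). With
$K \le 20$ the subsets are enumerated exhaustively — exact, and fast at
the panel sizes this package targets — rather than by the stochastic
search needed for larger panels. Marginal inclusion probabilities are the
summed posteriors of models containing each factor.

## The simulator

`simulation_spec()` / `generate_two_sample()` emulate a two-sample linear
instrumental-variable study in one gene region: 200 instruments, of which
15 mutually weakly correlated ones ($R^2 \le 0.2$) carry effects of size
0.2 on three risk factors,

$$ X_1 = 0.2\textstyle\sum_{m=1}^{5} Z_{c_m} + V_1,\quad
   X_2 = 0.2\xi\sum_{m=6}^{10} Z_{c_m} + 0.2(1-\xi)\sum_{m=11}^{15} Z_{c_m} + V_2,\quad
   X_3 = 0.2\sum_{m=11}^{15} Z_{c_m} + V_3, $$

with unit-variance exposure errors correlated at 0.3,
$Y = \theta'X + Z'\alpha + U$, $\operatorname{var}(U) = 1$,
$\operatorname{cor}(V_k, U) = 0.2$ (confounding),
$\theta = (-1/3,\ 0,\ 1/3)'$, and per-variant direct effects
$\alpha_j \sim N(0, \kappa^2/n_Y)$ drawn once per replicate (the
random-effects reading of the overdispersion model; the alternative of
redrawing $\alpha$ per individual is not used). $\xi \in [0,1]$ tunes
phenotypic heterogeneity: at $\xi = 0$ factors 2 and 3 share instruments
and their effects are unidentifiable; at $\xi = 1$ each factor has its own
instruments. No re-standardization of $X_2$ is applied as $\xi$ varies —
its genetic variance share simply changes with $\xi$. Summary statistics
come from actual per-variant univariable regressions on simulated
individuals in two non-overlapping samples (exposures in sample 1, outcome
in sample 2), not from analytic shortcuts, and the risk-factor correlation
fed to the transform is the empirical exposure correlation from sample 1.

### The synthetic LD stand-in

A measured regional correlation matrix is deliberately not shipped;
`synthetic_ld()` generates a stand-in with the features that matter for
this method: variants group into perfect-LD clusters (real dense regions
contain many perfect proxies, which is what makes regional matrices
rank-deficient), clusters within an LD block correlate with AR(1) decay
0.65, blocks correlate at 0.1, giving a rank-30 matrix for $J = 200$. At
the 99.99% explained-variance threshold the transform therefore retains
about 30 components — the few-dozen-components regime typical of real
single-gene analyses. The 15 designated causal instruments are placed in
non-adjacent clusters so all pairwise $R^2 \le 0.2$ (maximum 0.178 at the
defaults).

What the stand-in does **not** emulate: the irregular block sizes, allele
frequency spectrum and long-range decay pattern of a measured matrix, or
sampling noise in a finite reference panel (the pipeline consumes the
generator's true matrix, as analyses with large reference panels
effectively do). Calibration levels that depend quantitatively on the LD
structure — most visibly the *size of the inflation* of the unrobust test
under overdispersion — therefore reproduce the qualitative phenomenon at a
stand-in-dependent level rather than a matrix-specific number.

## Numerical choices

* Eigenvalues below $10^{-12}\lambda_{\max}$ are never retained, and
  negative eigenvalues (possible after weighting a repaired LD matrix) are
  excluded from the explained-variance denominator. Loading signs are
  fixed by making each column's largest-magnitude entry positive.
* The Gram matrix $S$ is rejected if its condition number exceeds
  $10^{12}$, with advice to lower the variance threshold.
* $\theta$-minimization: BFGS with analytic gradients from an
  inverse-variance-weighted start, with jittered Nelder–Mead restarts on
  non-convergence. The robust alternation iterates to relative tolerance
  $10^{-6}$ (at most 100 iterations); the $\kappa^2$ bisection bracket is
  expanded geometrically until it contains the root.
* Pruning is greedy by smallest risk-factor p-value, ties broken by
  position then id, so results are reproducible; the significance screen
  (`p < 0.05`, strict) is applied after pruning.
* PSD repair clips negative eigenvalues at zero and rescales to unit
  diagonal; inputs asymmetric beyond $10^{-8}$ are rejected.
* Pipeline TSV outputs are written at 6 significant digits so a rerun with
  identical configuration, inputs and seed is byte-identical.

## Calibration study sizes

The packaged calibration tests and the acceptance script run the
simulation at the study conditions ($n_X = n_Y = 20000$, 200 instruments,
99.99% threshold) with 500 replicates per headline cell and 200 for the
secondary small-sample cell, which keeps each cell's Monte-Carlo standard
error on a 5% rejection rate below one percentage point. The
variance-formula check uses a reduced region (60 variants, rank 15) at
$n = 4000$ with 300 replicates. Per-cell seeds are derived from a master
seed by a fixed counter, so grids are reproducible and cells independent.

## What passing tests do and do not show

The simulator draws Gaussian instruments and errors, uses a block-styled
rank-deficient LD stand-in, and assumes the true LD matrix is known.
Passing calibration therefore demonstrates internal validity of the
estimator, the overdispersion correction and the conditional F reference
distribution under these conditions — not robustness to LD
mis-specification, allele coding errors, sample overlap, non-Gaussian
traits, or idiosyncratic (non-random) pleiotropy concentrated in a few
variants, none of which the overdispersion parameter is designed to
absorb. Known limitations shared with the underlying methodology: effect
estimates reflect small lifelong perturbations, not clinical-scale
interventions; the colocalization module assumes a single causal variant
per trait; and time-varying exposure effects are out of scope.
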