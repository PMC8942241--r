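---
title: "Unbiased estimation of QTL variance and heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased estimation of QTL variance and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlvar)
```

## The problem

QTL mapping and GWAS models treat the effect $\alpha$ of a locus as a fixed
regression coefficient, but report the locus's *size* as a variance,
$\sigma^2_\alpha = \alpha^2$ (on a standardized genotype scale), or as a
heritability.  Squaring the unbiased estimate $\hat\alpha$ does not give an
unbiased variance: since
$E[\hat\alpha^2] = \alpha^2 + s^2_{\hat\alpha}$, the naive squared-effect
estimate overstates the QTL variance by exactly the squared standard error
of the effect estimate.  The inflation is negligible in large samples but
substantial below a few hundred individuals — precisely the regime of many
designed crosses.  This bias is distinct from the Beavis effect (which
comes from conditioning on significance and is out of scope here): it
occurs even without any significance test.

`qtlvar` implements two routes to an unbiased estimate and the machinery
around them.

## Models

The trait model is the mixed model

$$ y = X\beta + z\alpha + \xi + \varepsilon, \qquad
   \xi \sim N(0, A\sigma^2_\xi), \quad
   \varepsilon \sim N(0, I\sigma^2), $$

where $z$ holds the per-individual genotype indicator of the tested locus
(+1 / 0 / −1 for the three genotypes of a biallelic locus), standardized to
sample mean 0 and sample variance 1, and $A$ is an additive relationship
(kinship) matrix normalized so that $\mathrm{tr}(A) = n$.  Interval-mapping
mode omits $\xi$.

**Fixed-QTL model** (`remlFitFixedQTL`): $z$ is a column of the fixed
design; $(\sigma^2_\xi, \sigma^2)$ are estimated by REML and
$\hat\alpha$, $s_{\hat\alpha}$ come from generalized least squares at the
REML variances.  The *moment estimator* corrects the squared effect:

$$ \hat\sigma^2_\alpha = \hat\alpha^2 - s^2_{\hat\alpha}, $$

optionally truncated at zero (`momentQTLVariance`).  The untruncated form
is unbiased; the truncated form is what one reports.

**Random-QTL model** (`remlFitRandomQTL`): $\alpha \sim N(0,
\sigma^2_\alpha)$, so the variance of $y$ is
$V = zz^\top\sigma^2_\alpha + A\sigma^2_\xi + I\sigma^2$ and the QTL
variance is estimated directly as a component, by maximizing the restricted
log-likelihood

$$ L(\theta) = -\tfrac12\ln|V| - \tfrac12\ln|X^\top V^{-1}X|
   - \tfrac12 (y - X\hat\beta)^\top V^{-1} (y - X\hat\beta). $$

We use this likelihood exactly as written (natural logs, no additive
constant); only likelihood *differences* are ever interpreted, so the
constant convention cancels in the likelihood-ratio statistic
$\mathrm{LRT} = -2(L_0 - L_1)$.

The heritability of the locus is
$h^2_{QTL} = \sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_\xi + \sigma^2)$
(`qtlHeritability`), with a delta-method standard error propagated from the
inverse Fisher information of $\hat\theta$ through the contrasts
$X = L_X^\top\theta = \hat\sigma^2_\alpha$ and $Y = L_Y^\top\theta$ (total
variance) (`deltaSEHeritability`).

## How close are the two routes?

At the random model's own optimum the first-order condition gives
*exactly* $\hat\sigma^2_\alpha = \hat\alpha^2(\hat\theta_2) -
s^2(\hat\theta_2)$, where $\hat\alpha(\theta_2)$ and $s^2(\theta_2)$ are
the GLS effect estimate and its variance computed at the random model's
background components $\theta_2 = (\sigma^2_\xi, \sigma^2)$.  This follows
from decomposing the restricted likelihood along the error contrast that
estimates $\alpha$:

$$ L_3(\sigma^2_\alpha, \theta_2) = L_2(\theta_2)
   - \tfrac12\ln\!\big(\sigma^2_\alpha + s^2(\theta_2)\big)
   - \tfrac12\,\frac{\hat\alpha(\theta_2)^2}{\sigma^2_\alpha + s^2(\theta_2)}
   + \text{const}. $$

Without a polygene the equivalence to the fixed-model moment estimate is
exact (the contrast structure does not depend on $\theta_2$), and the unit
tests assert it to $10^{-4}$ and better.  With a polygene the fixed model
estimates $\theta_2$ with $z$ in the design while the random model
maximizes jointly, so the two background estimates — and hence the two QTL
variance estimates — differ by $O(1/n)$.  At $n = 278$ the difference is
below the fourth decimal; at $n = 50$ (ten full-sib families of five) the
replicated experiments in this package show a median absolute gap of about
$5\times10^{-3}$ on a variance scale of 1–5, i.e. the two estimates lie on
the diagonal of a scatter plot but are not numerically identical.
`runEquivalenceExperiment` measures the agreement fraction at a
user-chosen tolerance and reports REML boundary flags alongside, since
truncated pairs at zero agree exactly.

## Goodness-of-fit measures

For the single-marker regression without a polygene,
$s^2_{\hat\alpha} = \hat\sigma^2/(n-1)$ under our standardization, and the
corrected heritability coincides *identically* with the adjusted
$R^2$ while the raw $R^2$ strictly exceeds it whenever
$\hat\sigma^2 > 0$ (`r2Family` asserts both).  The pseudo-$R^2$,
$1 - \exp(-\mathrm{LRT}/n)$, sits between the corrected and the naive
heritability on typical data (`pseudoR2`).  The multi-level moment
estimator $(\sum_k\hat\alpha_k^2 - \mathrm{tr}\,\mathrm{var}(\hat\alpha))/k$
(`momentVarianceMultilevel`) extends the correction to a random effect
whose $k$ levels are estimated as fixed coefficients, and
`ldPartitionedVariance` computes per-locus variances in multi-locus models
with linkage disequilibrium — under the fixed-effect treatment the
per-locus terms contain cross-locus products and can be negative under
antagonistic LD (they are reported as-is); under the random-effect
treatment each standardized locus contributes $\alpha_k^2$.

## Numerical choices

* **Standardization** uses the $n-1$ denominator sample standard
  deviation.  The source material does not state the denominator; $n-1$ is
  what makes $s^2_{\hat\alpha} = \hat\sigma^2/(n-1)$ and the adjusted-$R^2$
  identity exact, so it is forced by internal consistency.  Missing codes
  are mean-imputed with a message.
* **Optimization.**  The residual variance is profiled analytically.
  Two-component fits ($A\sigma^2_\xi + I\sigma^2$) rotate onto the kinship
  eigenbasis once and do a bracketed one-dimensional search over
  $\log\lambda_\xi$ (grid then Brent), making each likelihood evaluation
  $O(n)$ after the $O(n^3)$ eigendecomposition.  Three-component fits use
  Nelder-Mead over $(\log\lambda_\alpha, \log\lambda_\xi)$ started from the
  fixed fit's moment estimate, followed by coordinate-wise Brent
  refinement; log-scale parameters enforce positivity.  Convergence is
  declared at a relative likelihood change below $10^{-10}$.
* **Boundaries.**  A candidate solution with
  $\hat\sigma^2_\alpha \approx 0$ triggers a refit without the QTL
  component; if the restricted likelihood does not improve, the component
  is pinned at zero, the fit is flagged `boundary`, and the covariance
  entries of the pinned component are reported as `NA` rather than zeros
  (the information matrix is not valid for a parameter on the boundary).
* **Covariance of $\hat\theta$** is the inverse *expected* (Fisher)
  information $\tfrac12\mathrm{tr}(PV_iPV_j)$ at the optimum.  Software
  that uses observed information will differ slightly; the unit suite
  checks agreement with a finite-difference Hessian within 5%.
* **Identifiability.**  A kinship equal to the identity makes
  $\sigma^2_\xi$ and $\sigma^2$ indistinguishable (e.g. full-sib blocks
  with one sibling per family); the fitters detect this and stop with an
  explicit error.  Collinearity of the marker with covariates raises an
  error rather than silently dropping a column.
* **Pseudo markers** are filled with the conditional expectation of the
  {+1, 0, −1} code given the flanking genotypes under a Haldane map
  (Haley–Knott expected codes), computed by summing over ordered haplotype
  pairs of the two F2 gametes.  The imputation is isolated in one function
  so an alternative (e.g. multipoint HMM) can be swapped in.  Bonferroni
  thresholds count real markers only; pseudo markers are tested but do not
  enter the denominator.

## What the simulators emulate

`simulateF2SingleMarker` draws genotypes from the 1:2:1 F2 segregation,
standardizes per replicate with sample moments, and adds Gaussian noise:
defaults $\mu = 10$, $\sigma^2 = 20$, matching the replicated
single-marker experiments.  `simulateFullsibPolygenic` adds a polygenic
value per individual as family effect + within-family deviation, each with
variance $\sigma^2_\xi/2$, so the within-family covariance is
$\sigma^2_\xi/2$ — exactly the compound-symmetry structure implied by the
full-sib numerator matrix; defaults $\sigma^2_\xi = \sigma^2 = 10$ and
$\mu = 0$ (the population mean is not stated for this design; it is
irrelevant to all estimators because an intercept is always fitted).  The
QTL effect is set from the target heritability via
$\alpha^2 = (\sigma^2_\xi + \sigma^2)\,h^2/(1-h^2)$.

The generators emulate ideal conditions: no segregation distortion, no
missing genotypes, no dominance, unlinked background loci summarized by an
exact block kinship, Gaussian residuals.  Passing tests therefore
demonstrate the estimators' statistical properties under the model's own
assumptions, not robustness to genotyping error, selection, or
non-normality in real data.

The full replicated designs run heritability from 0 to 0.2 in steps of
0.001 with 500 replicates per point; the test suite uses the same designs
on a coarsened grid (two to four heritability values, 100–500 replicates,
sample sizes 25–250) so that the whole suite completes in a few minutes —
the coarsening changes Monte-Carlo resolution, not the design.  One seeded
generator drives each experiment, with replicates drawn sequentially from
the stream, so every experiment is reproducible from its design object.

## A worked example

```{r}
# moment correction on published fixed-model estimates
mm <- momentQTLVariance(0.5278, 0.1122)
mm
qtlHeritability(mm, 3.5054, 0.3842)

# bias experiment at a small sample size
design <- simulationDesign("f2_single_marker", n = 25,
                           h2_grid = c(0.05, 0.15),
                           n_replicates = 200, seed = 1)
runBiasExperiment(design)$summary[, c("h2_true", "alpha2_true",
                                      "mean_naive", "mean_moment",
                                      "mean_s2")]
```

## Limitations

* Gaussian traits only; no generalized mixed models, no multi-trait
  models, no heterogeneous residual structures ($R = I$ is fixed).
* Kinship matrices are dense; fits are intended for $n$ up to a few
  thousand.
* The delta-method heritability SE is available only from random-model
  fits: under the fixed model the covariance between
  $\hat\sigma^2_\alpha$ and the background components is not estimable,
  so fixed-model heritabilities carry no standard error.
* The moment correction addresses squared-effect bias only; bias from
  conditioning on significance (the Beavis effect) needs a separate
  truncation correction and is not implemented here.
* Genotype input is the three-code biallelic format; VCF/PLINK ingestion,
  dominance coding, and general pedigree numerator matrices are out of
  scope.
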