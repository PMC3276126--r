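---
title: "Variance components, heritability and Qst from open-pollinated progeny trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components, heritability and Qst from open-pollinated progeny trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstreml)
```

## The model

`qstreml` analyses common-garden progeny trials in which open-pollinated
(OP) families collected across a species' native range are grown together
in a resolvable incomplete block design.  The individual-tree mixed model
for a trait $y$ is

$$
y_{ijklm} = \mu + R_j + b_{jk} + s_i + f_{il} + e_{ijklm},
$$

with replicate $R_j$ fixed, incomplete block within replicate
$b_{jk} \sim N(0, \sigma^2_b)$, subrace (the population unit)
$s_i \sim N(0, \sigma^2_s)$ — fitted as a fixed effect when only
within-population parameters are wanted, and as random whenever
$\sigma^2_s$ itself is of interest — and family within subrace
$f_{il} \sim N(0, \sigma^2_f)$.  Estimation is restricted maximum
likelihood (REML), so variance components are free of the bias induced by
estimating the fixed effects.

Because OP progeny have unknown, mixed paternity with some selfing and
biparental inbreeding, sibs are more related than paternal half-sibs.
The family variance is converted to additive genetic variance with a
relatedness coefficient $r$,

$$
\hat\sigma^2_{add} = \hat\sigma^2_f / r, \qquad r = 0.4 \text{ by default},
$$

rather than the outcrossed half-sib value $r = 0.25$.  From a single
subrace-random fit the package derives, per trait:

* $h^2_{op} = \sigma^2_{add} / (\sigma^2_f + \sigma^2_e)$, the
  open-pollinated narrow-sense heritability.  The phenotypic denominator
  excludes the replicate and incomplete-block variance (design nuisance);
  `include_iblock = TRUE` adds the block term for users who prefer the
  wider denominator.
* $CV_a = 100\sqrt{\sigma^2_{add}}/\bar{y}$ and
  $CV_s = 100\sqrt{\sigma^2_s}/\bar{y}$, scale-free evolvability measures.
* $Q_{ST} = \sigma^2_s / (\sigma^2_s + 2\sigma^2_{add})$, the quantitative
  analogue of the marker fixation index $F_{ST}$.

Standard errors are first-order delta-method propagation of the
asymptotic covariance of the variance components (the inverse observed
information of the restricted likelihood at the optimum).  At a boundary
estimate the information matrix is singular and standard errors are
reported as unavailable rather than extrapolated.

## Divergence inference

A trait under spatially varying selection should show $Q_{ST}$ exceeding
the neutral-marker $F_{ST}$.  The one-tailed likelihood-ratio test fixes
the null $Q_{ST} = F_{ST}$ by tying the subrace variance to the family
variance at

$$
\sigma^2_s = \frac{2 F_{ST}}{1 - F_{ST}} \cdot \frac{\sigma^2_f}{r},
$$

the unique single-constraint implementation of that null, refits the
model under the tie, and refers twice the log-likelihood difference to a
50:50 mixture of a point mass at zero and $\chi^2_1$.  The one-sided
convention is direction-aware and continuous: when the unconstrained
estimate exceeds $F_{ST}$, $p = \tfrac12 P(\chi^2_1 \ge \Lambda)$;
otherwise $p = 1 - \tfrac12 P(\chi^2_1 \ge \Lambda)$, so a fit exactly on
the null gives $p = 0.5$.  $F_{ST}$ is a user-supplied scalar (0.09 by
default, with 0.158 as a sensitivity value); marker-based estimation of
$F_{ST}$ is out of scope.

Two further likelihood-ratio tests share the machinery: the
family-variance test (null model without the family term, boundary
mixture reference) and two-tailed tests of the additive and subrace
correlations (cross-covariance fixed at zero, $\chi^2_1$ reference, since
a covariance is an interior parameter).  REML likelihoods are only ever
compared between models with identical fixed-effect structure.

Calibration of the $Q_{ST}$ test is checked by simulation in the test
suite.  At the trial's own dimensions the subrace variance carries only
about 16 degrees of freedom, so the mixture reference is a small-sample
approximation; large simulations at the null (thousands of replicates,
cross-checked against an independent closed-form REML implementation for
the balanced nested case) put the true type-I error near 0.04 at a
nominal 0.05 — mildly conservative, never anti-conservative — with
essentially full power at effect sizes like $Q_{ST} = 0.40$ against
$F_{ST} = 0.09$.  The calibration simulation is the authoritative
description of this behaviour.

## Bivariate fits and correlations

Genetic correlations come from bivariate REML fits (models with more than
two traits are out of scope: they rarely converge on data of this
shape).  Each of the subrace, family and residual levels carries an
unstructured $2 \times 2$ covariance matrix parameterised by its
log-Cholesky factors, which enforces positive semi-definiteness and
bounds every implied correlation in $[-1, 1]$.  The incomplete-block
level is diagonal by default (no cross-trait block covariance) to aid
convergence; `iblock_structure = "us"` relaxes this.  Subrace is always
random in bivariate fits.  Trees with one missing response contribute
their marginal likelihood.

The additive genetic correlation $r_a$ is the family-level correlation
(the relatedness scaling cancels), $r_s$ the subrace-level one, and the
phenotypic correlation $r_p$ sums covariances over the subrace, family
and residual levels and divides by the total standard deviations.  The
block level is excluded from $r_p$: it is design noise and its
covariance is structurally zero under the default model, so including
its variance would bias $r_p$ towards zero by construction.

## The trial simulator

`simulate_trial()` draws data from the generative model above: phenotype
= grand mean + latitudinal cline + subrace deviate + family deviate +
replicate offset + block deviate + residual.  All random deviates are
normal — the standard mixed-model assumption, matching REML — with
multi-trait
deviates at the subrace, family and residual levels drawn from
configurable correlation matrices scaled by the per-trait standard
deviations (block deviates are independent across traits).  Replicate
effects are fixed offsets, defaulting to equally spaced values spanning
$\pm 0.5$ residual standard deviations, because the estimation model
treats replicate as fixed.  Families are assigned to incomplete blocks
at random within each replicate; the estimation model conditions on the
assignment, so an alpha-design-optimal layout would not change
correctness.  Two-tree plot labels are emitted for realism but carry no
variance, matching the fitted model, and each family contributes at most
one tree per replicate.  Missingness is completely at random.

The default configuration emulates the motivating study design: 17
subraces, 27 OP families per subrace, 5 trees per family over 5
replicates of 24 incomplete blocks, and a lignin-composition-like trait
with grand mean 1.97, $h^2_{op} = 0.44$ and $Q_{ST} = 0.34$ at $r = 0.4$.
The published per-trait summaries are not mutually consistent (the
printed additive variance, $CV_s$ and $Q_{ST}$ columns cannot all be
reproduced from one set of components), so the defaults prioritise the
heritability/divergence pair; `cv_subrace()` accepts any variance the
user prefers.  `sigma2_subrace` is the variance of subrace deviations
*around* the cline, hence the default cline slope is zero — with a
nonzero slope the total between-subrace variance exceeds the configured
value by `slope^2 * var(latitudes)`.  Latitudes are decimal degrees
South as positive magnitudes, so a positive slope means the trait
increases southward.

`overlay_measurement_error()` emulates a spectroscopically predicted
trait: independent normal noise sized against the observed phenotypic
variance so that the individual-level squared correlation between true
and predicted values equals the requested reliability.  Because the
noise is independent of all genetic effects, family means average it
away — the additive genetic correlation between a trait and its noisy
surrogate approaches 1 even at reliability 0.5, while the surrogate's
heritability is attenuated by roughly the reliability factor.  The
attenuation identity $h^2_{pred} = R \cdot h^2$ is exact when the
reliability base equals the heritability denominator; population spread
and block variance make it approximate, which is why the package's
simulation checks of this identity use configurations without
between-population variance.

What the simulator does **not** emulate: spatial autocorrelation and
competition between neighbouring trees, selfing as an explicit
mixed-mating process (inbreeding enters only through $r$), non-normal
trait distributions, and informative missingness.  Passing recovery and
calibration tests on simulated data therefore demonstrates correctness
of the estimation machinery under the stated model, not robustness to
these departures in field data.

## Numerical choices

The restricted likelihood is evaluated through the sparse mixed-model
equations: one symbolic Cholesky factorisation per data set, numeric
updates per evaluation.  Univariate fits profile out the residual
variance and optimise the variance ratios by quasi-Newton (`nlminb`)
with non-negativity bounds; this reaches the same optimum as
average-information iterations but with simpler, more robust code, and a
restart/Nelder-Mead escalation guards against premature convergence on
flat ridges.  Convergence is declared when a restart from the solution
cannot improve the objective beyond `1e-6`; multi-start reproducibility
of the log-likelihood to `1e-6` is asserted in the tests.  Components
converging to the lower bound are reported as zero with a boundary flag
(the same projection-to-zero behaviour as the standard REML packages in
this field).  Bivariate objectives are optimised on the log-Cholesky
scale with traits standardised internally to unit variance (the
likelihood is transformed back exactly).  Exactly duplicated traits make
the bivariate restricted likelihood unbounded along the singular ridge;
fits then stop a numerical whisker short of correlation one at every
level, which is the intended behaviour for that degenerate input.  (The
aggregate phenotypic correlation can sit a little further below one
there, because the per-trait variance split across levels is
unidentified along the ridge and the Cauchy–Schwarz aggregation is only
tight when the splits match.)

Cline analysis regresses per-subrace means on latitude by ordinary least
squares (unweighted by default; family counts can be supplied as
weights).  Least-squares means — the subrace fixed effect plus the
average replicate effect — are the default because the trial is
unbalanced; raw means are available.  With fewer than three subraces the
regression is refused.

## Problem sizes used by the checks

The simulation-based checks run at the trial's own dimensions (17
subraces × 27 families × 5 trees ≈ 2300 trees) with 200 replicates for
parameter recovery, 400 for type-I calibration and 200 for power;
measurement-error checks use 400-family trials with 5–40 replicates.
These sizes give Monte-Carlo standard errors comfortably inside the
tolerances asserted, while a full fit takes well under a second.
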