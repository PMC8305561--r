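---
title: "Models and methods for two-arm pre-post trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for two-arm pre-post trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepost)
```

## The design and the estimand

A two-arm randomized pre-post trial measures a continuous outcome
$Y_{ijt}$ on subject $i$ of arm $j \in \{0, 1\}$ (0 = control,
1 = treatment) at baseline ($t_0$) and once after treatment ($t_1$), with
$n_0$ and $n_1$ subjects per arm. Randomization makes the two arms share
one baseline mean $\mu_{t_0}$ and one baseline variance $\sigma_0^2$. The
estimand throughout is the difference in mean post-treatment outcomes,

$$\tau = \mu_{1t_1} - \mu_{0t_1}.$$

Because randomization balances baselines in expectation, the
change-score effect (difference in mean post-minus-baseline changes) and
the slope-difference effect under a $t \in \{0,1\}$ time coding both equal
$\tau$, so six superficially different analyses all target one quantity
and can be compared head to head. The percent-change metric does *not*
fit this framework: it is a ratio statistic with a skewed distribution,
it is asymmetric in its reference value (`percent_asymmetry()`), and it
does not add over periods (`compound_percent()`). `effect_estimates()`
reports it for description only and the package attaches no
normal-theory inference to it.

Two population regimes are distinguished. In the *homogeneous* regime
every subject shares one pre/post covariance: post SD $\sigma_1$ and
pre-post correlation $\rho$. In the *heterogeneous* regime the arms have
their own post SDs $\sigma_{01}, \sigma_{11}$ and correlations
$\rho_0, \rho_1$ (a common baseline SD $\sigma_0$ is kept — randomization
guarantees it). The quantity

$$\beta_3 = \frac{\rho_1\sigma_{11} - \rho_0\sigma_{01}}{\sigma_0}$$

is the difference between the arms' regression slopes of post on
baseline; it is the single number that controls everything specific to
the heterogeneous regime.

## The six analyses

| method | model | estimator of $\tau$ |
|---|---|---|
| `anova_post` | post ~ arm | raw post mean difference |
| `ancova_i` | post ~ arm + baseline | post difference minus common slope × baseline imbalance |
| `ancova_ii` | post ~ arm * centered baseline | post difference minus arm-specific slopes × centered baseline means |
| `anova_change` | (post − baseline) ~ arm | difference-in-differences |
| `fit_rm` | joint GLS, saturated means | difference-in-differences (exactly) |
| `fit_crm` | joint GLS, equal baseline means | GLS analogue of the ANCOVA adjustment |

Three exact identities tie the table together and are enforced by tests:
the RM interaction coefficient equals the change-score
difference-in-differences for *any* covariance estimate (the mean model
is saturated); the pooled-covariance cRM estimate equals the ANCOVA-style
adjustment with slope $\hat\Sigma_{01}/\hat\Sigma_{00}$ evaluated at the
REML covariance; and with no baseline imbalance every baseline-adjusted
estimator collapses to the raw post difference.

Efficiency in the homogeneous regime is governed by two deltas
(`delta1()`, `delta2()`):

$$\Delta_1 = \sigma_0^2 - 2\rho\sigma_0\sigma_1, \qquad
  \Delta_2 = (\sigma_0 - \rho\sigma_1)^2 \ge 0.$$

$\Delta_1$ compares ANOVA with the change-score analysis (ANOVA wins when
$\rho < \sigma_0/(2\sigma_1)$); $\Delta_2$ says the change-score analysis
never beats baseline-adjusted ANCOVA/cRM. At the package's homogeneous
preset ($\sigma_0 = 14$, $\sigma_1 = 15$, $\rho = 0.9$), $\Delta_1 = -182$
(ANOVA is far worst) and $\Delta_2 = 0.25$ (ANCOVA barely beats the
change score).

In the heterogeneous regime the interaction model is the correctly
specified one, and its unconditional variance is never larger than the
main-effect model's, with equality exactly in balanced designs
(`true_variance()` implements both closed forms; the allocation
proportions $p_j = n_j/(n_0+n_1)$ enter the main-effect formula through
the $(\beta_3 p_{1-j})^2\sigma_0^2$ residual-inflation terms).

## Standard errors: conditional versus unconditional

OLS treats baselines as fixed, so its model-based variance is a
*conditional* variance; the scientifically relevant one is the
*unconditional* variance, averaging over the baseline distribution. The
package exposes the full menu and the theory of when each is right:

* **model** — the OLS/REML plug-in. Valid unconditionally for
  `anova_post` and `anova_change` always, and for `ancova_i` in the
  homogeneous regime. Under heteroscedasticity it acquires the asymptotic
  gap `ols_bias_delta()` $= (\sigma^2_{\epsilon 0} - \sigma^2_{\epsilon 1})
  (1/n_1 - 1/n_0)$, zero in balanced designs, positive (SE overstated)
  when the larger-residual-variance arm is the larger arm.
* **hc0–hc3** — sandwich flavors; `hc2` (leverage weight $1/(1-h_{ii})$)
  is the default robust choice on finite-sample grounds. These repair
  heteroscedasticity but, for the interaction model, still miss one term:
* **ahc** — the interaction model centers the baseline at the *estimated*
  pooled mean, and treating that mean as known understates the
  unconditional variance by `unconditional_inflation()` $=
  \beta_3^2\sigma_0^2/(n_0+n_1)$. The adjusted flavor adds the sample
  version $\hat\beta_3^2 \hat\sigma_0^2/(n_0+n_1)$ to the HC2 variance and
  is the recommended flavor for `ancova_ii`.
* **bootstrap** — stratified pairs resampling (subjects with replacement
  within arm, preserving $n_0, n_1$; stratification keeps the design
  quantities fixed, which is the natural resampling scheme for a
  randomized design). Default $B = 5000$; degenerate resamples are
  redrawn and counted, with failure above 1%.
* **reml** — the GLS plug-in $(X'V^{-1}X)^{-1}$ at the REML covariance.

p-values are two-sided t with the residual df for OLS flavors (HC flavors
reuse the model df, the common finite-sample practice) and a containment
convention, $n_0 + n_1$ minus the number of mean parameters, for GLS
fits. The exact small-sample covariance-inflation adjustment used by some
mixed-model software is not reproduced; at the sample sizes the presets
use ($n \ge 180$) the difference is negligible, and this limitation is
deliberate and documented rather than approximated.

Two residual-df conventions circulate for the ANCOVA models ($n-p$
versus one less). The package always uses $n - p$ (ANCOVA I: $n-3$,
ANCOVA II: $n-4$), the unbiased-OLS convention; the alternative is
available explicitly via `df_convention = "tables"` and is never applied
silently.

## REML/GLS numerics

With two time points and complete cases, each subject of arm $j$
contributes an identical $2 \times k$ design block, so the restricted
likelihood depends on the data only through per-arm sufficient
statistics ($n_j$, mean vector, centered SSCP). All GLS algebra runs on
those — a likelihood evaluation is $O(1)$ in the sample size, which is
what makes the Monte Carlo engine cheap.

For the saturated (`rm`) mean structure REML has a closed form: the
pooled within-arm sample covariance with denominator $n_0+n_1-2$
(pooled) or the per-arm sample covariances with denominators $n_j - 1$
(`by_arm`); the closed form is cross-checked against the numerical
maximizer in the test suite. For the constrained (`crm`) structure the
profiled restricted likelihood is maximized by BFGS in
$(\log \mathrm{SD}, \log \mathrm{SD}, \operatorname{atanh}\rho)$
coordinates — the transform keeps every iterate positive definite, so no
step-halving machinery is needed — initialized at the closed-form
saturated estimate (which is nearly optimal), relative tolerance
$10^{-12}$, at most 200 iterations. Maximum likelihood (biased)
covariance estimation is deliberately unavailable. Degenerate inputs
(a sample pre-post correlation of 1, zero variances) are refused with a
positive-definiteness error rather than regularized.

Ties and edge cases elsewhere: a zero SE with a zero estimate reports
$t = 0, p = 1$ (the identical-arms limit); rank-deficient designs name
the collinear column; leverage 1 makes HC2/HC3 undefined and says so.

## The synthetic-data generator

`generate_trial()` draws each arm from the bivariate normal implied by a
`scenario_params` object. The three `scenario_preset()`s *are* the study
conditions everything else is verified under: baseline 88 (SD 14), post
86/83 (SD 15), $\tau = -3$, correlation 0.9 (homogeneous), or 0.9/0.7 by
arm (heterogeneous), with $n = (90, 90)$ or $(60, 120)$. Each arm uses
its own RNG substream derived deterministically from `(seed, arm)`, so
arm draws are independent, reproducible, and the control arm's data do
not change when the treatment arm's configuration does. `null_variant()`
zeroes the effect while keeping the covariance, for type-I-error
experiments.

What the generator deliberately does *not* emulate: non-normal outcomes,
missing measurements, more than two arms or time points, or
baseline-dependent variance patterns. Tests passing under these
conditions therefore certify the estimators' algebra and their
normal-theory calibration; they say nothing about robustness to
skewness or attrition, which are outside the package's scope (complete
cases are required at validation, not dropped silently).

## The Monte Carlo engine and its resolution

`run_mc()` generates `R` trials (replicate seeds are substreams of the
master seed, so runs are reproducible and order-independent), analyzes
each, and reports per method × flavor: bias, empirical SD, mean
estimated SE, relative SE bias (mean SE / empirical SD − 1), 95% CI
coverage, and rejection at $\alpha = 0.05$ — each with its Monte Carlo
standard error (binomial for proportions; $s/\sqrt{R}$ for means;
$s/\sqrt{2(R-1)}$, the normal-theory approximation, for the empirical
SD; a delta-method combination for the relative SE bias).

The default `R = 2000` puts about 0.005 of MC-SE on a rejection rate and
about 1.6% on an empirical SD — enough to resolve every effect the
theory module predicts at the presets except one: the homogeneous-regime
gap between ANCOVA and the change score is $\Delta_2 (1/n_0 + 1/n_1) =
0.0056$ on the variance scale, comparable to its own paired MC noise.
The test suite therefore checks that ordering as a *paired* variance
difference (the two estimators are evaluated on the same replicates,
which removes most of the noise) at the same 3-MC-SE resolution used for
every other simulation comparison, rather than as a strict inequality
between two marginal SDs. Problem sizes used by the checked experiments:
$R = 2000$ at the preset $n$ of 180 for bias/SD/calibration/type-I
claims, $R = 500$ per point of the $n \in \{40, 160, 640\}$ grid for the
ANCOVA/cRM convergence claims, and $10^5$ subjects per arm for generator
moment checks.

`se_calibration()` compares each flavor's relative SE bias against the
sign predicted by `ols_bias_delta()` (minus the centering inflation for
the interaction model); `equivalence_gap()` tracks the median absolute
difference between asymptotically equivalent estimator pairs as $n$
grows — identically zero at every $n$ for change-score/RM, shrinking for
ANCOVA I/cRM-pooled and ANCOVA II/cRM-by-arm.

```{r example}
report <- run_mc(scenario_preset("heterogeneous_unbalanced"),
                 methods = c("ancova_i", "ancova_ii"), R = 200, seed = 42)
se_calibration(report)
```

(A small `R` is used here so the vignette builds quickly; the package's
tests run the full-resolution versions.)

## Design choices that were genuinely open

* **Bootstrap stratification.** Resampling is within-arm; unstratified
  resampling would make $n_0, n_1$ random, which contradicts the design.
* **Substream RNG.** A counter-style derivation `(seed, stream)` rather
  than one global stream: it buys arm- and replicate-level independence
  and reproducibility at no cost.
* **Residual-df and GLS-df conventions** as described above; both chosen
  for transparency over software mimicry.
* **Heteroscedasticity advisory.** ANCOVA fits attach a note when the
  arm residual-variance ratio leaves $[0.5, 2]$ in an unbalanced design —
  the configuration in which the model-based SE is actually biased — and
  recommend the hc2/ahc flavors.
* **Percent change.** Reported, never tested: no SE or p-value is
  attached to `tau_pct` anywhere.

## Limitations

Single baseline covariate only (no additional covariates), two arms, two
time points, complete cases, normal-theory generator. The GLS df
convention is approximate in very small samples. The heterogeneous cRM
fit estimates a free $2\times2$ covariance per arm and does not impose
the common baseline variance that randomization implies; at the preset
sample sizes the efficiency cost is negligible.
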