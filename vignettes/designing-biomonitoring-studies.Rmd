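---
title: "Designing biomonitoring-based epidemiology studies under classical measurement error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biomonitoring-based epidemiology studies under classical measurement error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomonpower)
```

## The measurement error model

Every calculator in this package works under one model. A subject $i$ has a
true long-run mean exposure $X_i$ on the ln scale, distributed across the
population as $X_i \sim N(\mu, \sigma^2_B)$ — $\sigma^2_B$ is the
*between-person* variance. A single measurement on that subject is
$W_{ij} = X_i + \varepsilon_{ij}$ with
$\varepsilon_{ij} \sim N(0, \sigma^2_W)$ independent of $X_i$ and of the
outcome — classical, additive, homoscedastic, non-differential error. The
*within-person* variance $\sigma^2_W$ lumps temporal biological fluctuation
with assay noise; for short-lived urinary biomarkers it routinely dwarfs
$\sigma^2_B$. Averaging $m$ measurements shrinks the error variance to
$\sigma^2_W/m$.

The exposure mean $\mu$ is fixed at zero throughout without loss of
generality: none of the quantities computed here (correlations,
attenuation factors, powers, sample sizes) depend on it, and in the
logistic simulator any location shift is absorbed exactly by the calibrated
intercept.

Two reliability summaries follow. The intraclass correlation coefficient
$$\mathrm{ICC} = \frac{\sigma^2_B}{\sigma^2_B + \sigma^2_W}$$
is the reliability of a *single* measurement, and the validity coefficient
$$\rho^2(m) = \frac{\sigma^2_B}{\sigma^2_B + \sigma^2_W/m}$$
is the squared correlation between the true mean and an $m$-measurement
person-mean; $\rho^2(1) = \mathrm{ICC}$ and $\rho^2 \to 1$ as $m$ grows.

Some pilot studies report an ICC together with a total variance rather
than the components. `vc_from_icc()` converts, and its
`total_is_between` switch covers the "best-case" reading in which a
published total that cannot be decomposed is treated as $\sigma^2_B$
itself, with $\sigma^2_W = \sigma^2_B(1-\mathrm{ICC})/\mathrm{ICC}$ layered
on top. Both bundled triclosan fixtures use that reading; it is
deliberately optimistic (highest power, least bias), so design conclusions
drawn from it are conservative in the direction that matters.

## Repeats for a target validity

Inverting $\rho^2(m)$ gives the reliability formula
$$m = \frac{\rho^2 (1-\mathrm{ICC})}{\mathrm{ICC}(1-\rho^2)}.$$
`repeats_for_validity()` returns both the real-valued solution and its
ceiling. The ceiling is the right presentation for a design decision:
any smaller whole number of samples leaves the validity below target
(rounding 17.05 to 17, for instance, would miss a 0.9 target at ICC 0.2).
The boundaries $\mathrm{ICC}, \rho \in \{0,1\}$ are rejected rather than
returning infinities — the formula diverges there, and a design question at
those values is ill-posed.

## Attenuation of linear-regression slopes

Regressing a continuous outcome on the person-mean $\bar W_i$ multiplies
the expected slope by the regression-dilution factor
$$\lambda(m) = \frac{m\,\sigma^2_B}{m\,\sigma^2_B + \sigma^2_W},$$
so the expected percent bias is $(1-\lambda)\times 100\%$, equal to
$(1-\mathrm{ICC})\times 100\%$ at $m=1$. `repeats_for_max_bias()` solves
$\text{bias} \le b$ in closed form,
$m \ge \sigma^2_W(100-b)/(\sigma^2_B\, b)$, and rounds up. The arithmetic
is followed exactly: at $\sigma^2_B = 0.21$, $\sigma^2_W = 0.72$ the bias
at $m = 30$ is 10.26% and at $m = 31$ it is 9.96%, so the smallest number
of repeats meeting a 10% cap is 31 — a scan over $m$ in the test suite
confirms the closed form case by case. $\sigma^2_B = 0$ is rejected
rather than silently returning zero: attenuation (and every design formula
downstream) is undefined for a biomarker with no between-person signal.

These formulas address the location of the estimated slope only; naive
analysis also *understates the variance* of the estimate, so confidence
intervals from an unadjusted model are too narrow. The calculators size
studies around the bias and the power loss; they do not repair the
intervals.

## Sample size, detectable effect, power

For a continuous outcome with marginal variance $\sigma^2_y$ and true slope
$\beta$ per ln(exposure) unit, the error-free requirement is
$$n_x = \frac{(z_{1-\alpha/2} + z_{\text{power}})^2\,
        (\sigma^2_y - \beta^2\sigma^2_B)}{\beta^2\sigma^2_B},$$
and classical error inflates it to $n_z = n_x / \rho^2(m)$. Conventions,
each of which the tests pin down:

* **Residual-variance numerator.** $\sigma^2_y - \beta^2\sigma^2_B$, not
  $\sigma^2_y$: the outcome variance net of the exposure effect is what
  opposes detection. The distinction is immaterial when the effect explains
  a trivial share of the outcome variance, which is the regime these
  designs live in, but the convention must be fixed for the integer answers
  to be stable.
* **Rounding.** $n_z$ is rounded half-up to the nearest whole subject
  (`round_half_up`), not ceilinged; the sub-subject remainder is far inside
  the precision of any variance-component estimate. A consequence probed in
  the tests: at the rounded $n$, analytic power can sit a hair under target
  (by $<10^{-4}$) when the rounding went down.
* **Normal quantiles**, not $t$: at the cohort sizes these calculators
  produce the difference is below half a percent, and the closed form stays
  invertible.
* **Presets.** `test_spec_confirmatory()` ($\alpha=0.01$, power $0.90$) and
  `test_spec_exploratory()` ($\alpha=0.05$, power $0.80$), named for the
  two design postures; every function also takes an explicit `test_spec()`.

`mde_for_n()` is the exact algebraic inverse of the unrounded $n_z$:
$$\beta_{\min} = z_{\text{tot}}
  \sqrt{\frac{\sigma^2_y}{\sigma^2_B\,(n\rho^2(m) + z_{\text{tot}}^2)}},
  \qquad z_{\text{tot}} = z_{1-\alpha/2} + z_{\text{power}}.$$
The test suite verifies the inversion against an independent bisection on
the sample-size function to $10^{-6}$ over randomized parameter sets, and
validates the whole chain empirically: simulating studies at the computed
$n$ yields a rejection rate within Monte-Carlo error of the target power
(with the effect sized to explain about 1% of outcome variance, where the
residual-variance convention is exact). `power_for_design()` presents the
same relationship solved for power, and `sample_size_inflation()` tabulates
$n_z/n_x = 1/\rho^2$ as a function of ICC and $m$ alone.

## The logistic-regression simulator

Bias and power of logistic regression under classical exposure error have
no closed form, so `run_power_bias()` estimates them by simulation. Each
replicate draws $x_i \sim N(0, \sigma^2_B)$, an observed person-mean
$w_i = x_i + \bar\varepsilon_i$ with
$\bar\varepsilon_i \sim N(0, \sigma^2_W/m)$, and
$y_i \sim \text{Bernoulli}(\text{logit}^{-1}(\beta_0 + \log(\mathrm{OR})\,x_i))$,
then fits a maximum-likelihood logistic regression of $y$ on $w$ and
records the estimated OR and the two-sided Wald p-value — the analysis a
standard software fit reports.

Design choices that needed pinning down:

* **Intercept calibration.** "Baseline incidence $p_0$" is read as the
  *marginal* incidence of the cohort, so $\beta_0$ solves
  $E_X[\text{logit}^{-1}(\beta_0 + \log(\mathrm{OR})X)] = p_0$, evaluated
  by 64-node Gauss–Hermite quadrature and solved by bracketed root finding
  to a residual below $10^{-10}$ (`calibrate_intercept()`). The naive
  $\beta_0 = \text{logit}(p_0)$ fixes instead the incidence of a subject at
  the exposure mean; the two differ only in the second order at moderate
  $\sigma^2_B$, but the convention must be explicit. A Monte-Carlo oracle
  in the tests confirms the calibrated intercept reproduces $p_0$ to
  $10^{-3}$ at $10^6$ draws.
* **Replicate accounting.** Cohorts with all-0/all-1 outcomes, fits that do
  not converge, and effectively separated fits (Wald SE above 100) are
  flagged and excluded from both the power and the bias summaries, counted
  in `n_excluded`; a warning is recorded when exclusions pass 10%, and an
  error is raised only if nothing converges.
* **Summaries.** Power is the share of converged replicates with Wald
  $p < \alpha$; per-replicate percent bias is
  $100(\widehat{\mathrm{OR}} - \mathrm{OR})/\mathrm{OR}$, summarised by its
  median and empirical 2.5th/97.5th percentiles (linear interpolation
  between order statistics, `stats::quantile` type 7).
* **Reproducibility.** One root seed spawns independent L'Ecuyer-CMRG
  substreams, one per replicate (`parallel::nextRNGStream`), so results are
  bit-identical for a given spec and seed, would remain so under parallel
  execution, and the caller's RNG state is restored on exit.
* **Replicates.** The default `n_reps = 2000` pins power to roughly one
  percentage point at the low powers these designs produce
  ($\sqrt{0.07 \cdot 0.93/2000} \approx 0.006$); the bundled tests and the
  reproduction script use 2,000, with smaller counts only for monotonicity
  probes where direction, not level, is asserted.

The simulator is tied back to the closed forms wherever they overlap: for
small effects the median simulated OR sits at
$\exp(\log(\mathrm{OR}) \cdot \lambda(m))$ within Monte-Carlo error — at
the bisphenol case-study settings $\lambda = 0.368$ predicts a median bias
of $-7.9\%$, matching the simulation — and at $\mathrm{OR} = 1$ the Wald
p-values are uniform and the rejection rate sits at $\alpha$.

## What the simulated cohorts do and do not emulate

The generator reproduces exactly the world the design formulas assume:
normal ln-scale exposures, classical additive error, error-free outcomes,
no covariates. Passing tests therefore certify the calculators *under that
model*, not under skewed exposure distributions, multiplicative or
Berkson-type error, differential error, confounding, or outcome
misclassification — all of which occur in real cohorts and all of which are
out of scope here. For linear regression the outcome-variance input can
absorb outcome-side noise only if that noise is independent of exposure.

## Case-study fixtures

`inst/extdata/case-studies.yaml` stores the two bundled designs with a
`source` note per field. The bisphenol pregnancy cohort is parameterised by
explicit components ($\sigma^2_B = 0.21$, $\sigma^2_W = 0.72$, $n = 1379$,
$m = 2$, unit outcome variance, design slope 0.25); its reliability
section is run at ICCs 0.2 and 0.3, bracketing the component-implied 0.23.
The triclosan fixtures specify (ICC, total ln-variance) — mothers 0.6 and
0.019 with $n = 377$, boys 0.4 and 0.0095 with $n = 184$ — with the total
treated as $\sigma^2_B$ as described above, giving
$\sigma^2_W = 0.01267$ and $0.01425$. Their outcome scale is stored as a
variance of 6; the source material is ambiguous between a variance and a
standard deviation of 6, and the calculator-input convention (variance) is
kept. Since required $n$ scales linearly in $\sigma^2_y$ and the MDE as its
square root, a reader preferring the SD reading can rescale accordingly.
`run_case_report()` evaluates each fixture with the same exported functions
a user would call, so the report is a worked example, not a separate code
path.

## Known limitations

Variance components are taken as known constants; propagating their
estimation uncertainty (e.g. from a small pilot) is not attempted. The
Wald test is the only test offered for the logistic design, and rare
outcomes at small $n$ will show its usual small-sample distortions — the
exclusion bookkeeping makes such regimes visible rather than fixing them.
Cost-optimal allocation between more subjects and more repeats is not
implemented. All calculations are per a single exposure; multiple
correlated biomarkers are out of scope.
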