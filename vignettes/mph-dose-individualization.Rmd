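---
title: "Individualized methylphenidate dosing from a random-intercept logistic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized methylphenidate dosing from a random-intercept logistic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mphdose)
```

## The problem

Methylphenidate (MPH) response in children with ADHD is heterogeneous:
the same mg/kg dose that normalizes one child's Conners' Parent Rating
Scale (CPRS-R:S) score leaves another's above the diagnostic cutoff.
`mphdose` implements a two-step procedure that (i) estimates a
population dose-response model from longitudinal visit records, and
(ii) inverts it per patient — updating the patient's own random effect
as their visits accumulate — to recommend the dose expected to reach a
target improvement probability.

## The model

For patient $i$ at visit $j$, let $Y_{ij} = 1$ when the CPRS-R:S total
is at or below 40 ("improved": no longer meeting the ADHD criterion).
The model is a generalized linear mixed model with a logit link and a
patient-level random intercept:

$$
\mathrm{logit}\, P(Y_{ij} = 1) =
  \beta_0 + X_{ij}\beta + b_i + d \ln D_{ij},
\qquad b_i \sim N(0, \sigma^2),
$$

where $D_{ij}$ is the MPH dose in mg/kg and $X_{ij}$ holds covariates
(months on treatment, baseline severity centered at the cohort mean,
and any screened demographic or comedication terms). The log-dose term
makes the model invertible in closed form for $D$.

`mph_reference_params()` stores the reference estimates from a
historical cohort of 221 children: $\beta_0 = 1.9377$, time
$0.0800$/month, centered severity $-0.0512$/point (center 51.3817),
$d = 0.8610$, $\sigma^2 = 1.452$. These drive the worked examples and
serve as the simulation ground truth.

### Estimation: adaptive Gauss–Hermite quadrature

The marginal likelihood integrates $b_i$ out of each patient's
Bernoulli likelihood. `marginal_loglik()` evaluates each
one-dimensional integral by Gauss–Hermite quadrature after recentering
the nodes at the patient's posterior mode and rescaling them by the
posterior curvature there (the mode is found by a vectorized,
step-halving Newton iteration, and the whole construction is repeated
at every likelihood evaluation). With the random effect degenerate
($\sigma^2 = 0$) the expression collapses exactly to the plain
logistic log-likelihood, which the tests exploit.

`fit_glmm()` maximizes this likelihood by BFGS over
$(\beta_0, \beta, d, \ln\sigma)$, followed by a Newton polish with a
numerical Hessian; optimizing $\ln\sigma$ rather than $\sigma^2$ keeps
the variance positive without constrained optimization and avoids
boundary pathologies. Convergence requires a relative log-likelihood
change below $10^{-8}$ and a gradient $\infty$-norm below $10^{-5}$;
the `converged` flag reports the achieved state honestly rather than
optimistically. Standard errors come from the inverse numerical
Hessian; coefficient tests and intervals are Wald, odds ratios are the
exponentiated coefficients and interval endpoints, and the variance CI
is Wald on the $\ln\sigma^2$ scale, back-transformed (the construction
behind the reference model's asymmetric variance interval is not
documented, so we use the standard delta-method interval). The default
of 15 quadrature nodes reproduces a 20,000-point dense-quadrature
oracle to well below $10^{-8}$ on test cohorts; `lme4::glmer` with
`nAGQ = 15` agrees with the fitter to four decimals in the test suite,
serving as an independent cross-check rather than the implementation.

### Covariate screening

`univariable_screen()` mirrors the conventional observational-cohort
strategy: each candidate is fit alone (with the random intercept), and
candidates with Wald $p < \alpha$ (default 0.05) enter the joint
multivariable model. The screen uses the same random-intercept
structure as the final model so that the two columns of the resulting
table are comparable.

## Empirical-Bayes updating

`predict_b()` predicts a patient's $b_i$ from their accumulated
history at fixed population parameters. The default is the conditional
(posterior) mode, matching the behavior of the mixed-model software
family the reference estimates came from; a Gauss–Hermite posterior
mean (`method = "gh_mean"`) is provided because "adaptive
Gauss–Hermite prediction" is ambiguous between the two, and on
near-Gaussian posteriors they agree to a few hundredths. The Newton
solver starts at 0, halves steps until the penalized log-posterior
increases, and stops at a gradient below $10^{-10}$ (at most 100
iterations). A patient with no history gets $\hat b = 0$ exactly — the
population prior — which is what makes the first-visit dose
recommendation well defined.

## Dose inversion

Given a target improvement probability $p_0$, the recommended dose
solves the fitted equation for $D$:

$$
D = \exp\!\left\{
  \frac{\mathrm{logit}(p_0) - \beta_0 - X\beta - \hat b}{d}
\right\}.
$$

At the first visit $\hat b = 0$ and time is 0; at follow-up $n$ the
estimate $\hat b_{k,n-1}$ uses all visits before $n$
(`recommend_trajectory()` feeds the previously recommended dose back
as the administered dose unless the stream provides one). Plugging a
recommended dose back into the model returns exactly $p_0$ — an
algebraic identity the tests verify to $10^{-12}$.

### Choices that required judgment

- **Target $p_0$.** `compute_target_p0()` takes the 90th percentile
  (linear interpolation between order statistics,
  `stats::quantile(type = 7)`) of last-visit fitted probabilities,
  each patient evaluated at their own $\hat b$. The reference
  publication prints $p_0 = 0.9866$ ($\mathrm{logit} = 4.2990$), but
  its own worked dose tables are arithmetically consistent only with
  $\mathrm{logit}(p_0) \approx 0.622$ (back-solved from the first
  worked row); with 4.2990 an average patient would need ~15.5 mg/kg,
  roughly 95 times the scale of the printed recommendations. Both
  routes are exposed: the default derives $p_0$ from the fit, and
  `dose_target(logit_p0 = ...)` accepts an explicit value for
  replaying the worked examples.
- **Severity score at follow-up.** The printed dose equation names
  baseline severity, yet the worked doses are reproducible only with
  the current visit's CPRS-R:S score. `severity_mode` defaults to
  `"current"` (which is also the clinically sensible choice — the dose
  should respond to the child's present state); `"baseline"` is
  available and logged in every recommendation.
- **Safety clipping.** The raw inversion is an unbounded exponential,
  so recommendations are clipped to 0.01–2.0 mg/kg by default, with a
  `clipped` flag and the pre-clip value retained. Curves and
  replication calls can disable clipping (`clip = NULL`).
- **First visit time.** The initial-dose equation carries no time
  term (time 0); `recommend_trajectory()` honors whatever visit times
  the stream provides, since the worked examples label their first
  rows at month 1.

## The synthetic cohort generator

No patient-level data accompany the reference estimates, so
`generate_cohort()` provides the cohort every downstream stage is
tested against. It emulates the published cohort profile — 221
children, baseline severity drawn from $N(51.38, 10.82^2)$ truncated
to scores above the diagnostic cutoff (40, 81], $1 +
\mathrm{Poisson}(3.94)$ follow-ups after the baseline row, visit gaps
uniform on $[1, 2 \times 22.42/4.94]$ months (any strictly increasing
scheme with the right mean period would do), and binary responses
drawn from the model itself with severity entering as centered
baseline severity. Administered doses were never published, so the
default policy draws one log-uniform dose per patient on 0.1–1.5
mg/kg, bracketing cited clinical MPH doses and the scale of the worked
recommendations; random-walk and response-adaptive policies are
available for sensitivity work. Displayed per-visit CPRS-R:S scores
are synthesized consistently with the binary outcome (uniform 20–40
when improved, 41–70 otherwise) — display-level realism only, since
the generating law is the binary model. One root seed drives
per-patient substreams derived by counter, so a patient's draws do not
depend on cohort size or ordering.

What the generator does *not* emulate: CPRS-R:S item-level structure,
severity trajectories over time, informative visit timing or dropout,
dose titration correlated with response (under the default policy),
and covariate effects beyond those in the generating parameters.
Passing tests therefore demonstrate the correctness of the machinery
and the recoverability of the model under the stated design — not that
the reference coefficients describe any new clinical population.

Because baseline severity is truncated at the cutoff, its
population mean (about 54.4 for the default configuration) sits ~3
points above the untruncated 51.38; the generator's tests check the
empirical mean against the truncated-normal law, and `fit_glmm()`
defaults its centering constant to the realized sample mean so the
fitted intercept keeps the same interpretation.

## Simulation sizes

The test suite fits 24 replicate cohorts of 221 patients for the
parameter-recovery check (mean estimates of $d$, the time coefficient
and $\sigma^2$ within two Monte-Carlo standard errors of truth) and
200 reduced-size cohorts (60 patients) for the null-covariate
screening calibration; the acceptance script uses 100 replicates at
the full study scale for tighter Monte-Carlo precision. A single
221-patient fit converges in a couple of seconds.

## Known limitations

- The model is a random-intercept logistic regression: no random
  slopes, no pharmacokinetics, no adverse-event constraints — the dose
  that attains $p_0$ is not automatically a safe or licensed dose, and
  the 0.01–2.0 mg/kg clip is plumbing, not clinical guidance.
- $\hat b$ is a point prediction; its uncertainty is not propagated
  into the recommended dose.
- The published univariable odds-ratio table depends on the original
  (undeposited) records and cannot be reproduced; only the screening
  procedure itself is implemented and tested on synthetic cohorts.
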