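---
title: "Profiling hospital preference for laparoscopic surgery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hospital preference for laparoscopic surgery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Laparoscopic surgery (LS) has spread unevenly across hospitals: for the
same patient, one centre may operate laparoscopically where another would
open. `lapref` implements a profiling pipeline that (i) quantifies each
hospital's *preference* for LS after accounting for its patient case mix,
(ii) relates that preference — and hospital procedural volume — to
risk-adjusted operative mortality with proper allowance for the clustering
of patients within hospitals, and (iii) translates an adverse adjusted odds
ratio into an interpretable count of procedures per one excess operative
death. Because the nationwide registries this kind of analysis runs on are
access-restricted, the package ships a synthetic multi-hospital registry
generator that emulates their statistical structure, so every stage is
exercised and validated end to end on data with known truth.

# Models and procedures

## Patient-level risk adjustment and O/E ratios

Expected outcome probabilities come from a logistic risk model
$\Pr(y_{ij}=1) = \operatorname{expit}(\alpha + x_{ij}^\top\beta)$ applied to
each patient $j$ of hospital (or period) $i$. Indirect standardization then
compares observed with expected events,
$\text{O/E} = \sum_j y_{ij} \big/ \sum_j \hat p_{ij}$. The same statistic
serves two roles: with a mortality or complication model it profiles
*outcomes* (biannual tables, volume-category displays), and with an
LS-propensity model it profiles *treatment choice* (the preference score).
Coefficients may be loaded from configuration — the published risk models
for specific procedures live in external papers and are deliberately not
reproduced — or refitted on a registry with `fit_risk_model()`, in which
case the logistic score equations make the total O/E exactly 1 on the
fitting data; that identity is used as a correctness oracle in the tests.

## The preference score

A pooled logistic model for the LS-versus-open choice is built by forward
stepwise selection (likelihood-ratio entry at $p < 0.05$, removal at
$p \ge 0.10$) over patient-level candidates. Summing its predicted
probabilities over the patients of one hospital gives the case-mix-expected
LS count; the hospital's preference score is observed/expected. Categories
follow half-open thresholds: *active* iff score $\ge 2$, *standard* iff
$0.5 \le$ score $< 2$, *low* iff score $< 0.5$. The continuous variant
floors the score at 1, `max(score, 1)`, so hospitals at or below expected
use form the reference.

Design notes, where the procedure was genuinely open:

* **Which test drives stepwise selection.** The likelihood-ratio test was
  chosen over Wald or score tests for its invariance to parameterization
  and stability when estimates drift toward boundaries. Ties in p-value are
  broken by the larger statistic, then by column-name order, making the
  selection deterministic for a given data set.
* **Tiny expected counts.** A ratio estimator explodes as its denominator
  approaches zero, so hospitals with expected LS count below 0.5 are
  flagged `unstable`; they stay in the data but reports should treat their
  scores as low-confidence. Hospitals with expected count exactly zero get
  an undefined score and are excluded from preference analyses with a
  message.
* **Annual volume** is the 3-year patient count divided by 3; the
  supplementary-style displays restricted to volume $\ge 10$ are a display
  filter only, never an inferential one.
* **Quantiles** in group descriptives use linear interpolation (R type 7),
  recorded in the output's `quantile_type` attribute.

## Hierarchical outcome models

Both the volume-outcome and the preference-outcome analyses use a logistic
regression with a hospital random intercept,
$\operatorname{logit}\Pr(y_{ij}=1) = x_{ij}^\top\beta + u_i$,
$u_i \sim N(0, \sigma^2)$, fitted by maximizing the marginal likelihood
with *adaptive* Gauss–Hermite quadrature: each hospital's integrand is
centred at its posterior mode and scaled by the local curvature before the
quadrature rule is applied, so accuracy holds even for large clusters where
naive quadrature fails. One node recovers the Laplace approximation; the
default is 15 nodes, and estimates on the test fixtures move by less than
$10^{-3}$ between 15 and 25 nodes. At $\sigma = 0$ the marginal likelihood
reduces analytically to the ordinary logistic likelihood, which the
evaluator uses directly — another tested identity. Standard errors come
from the observed information (a numerical Hessian) of the marginal
log-likelihood at the optimum; when $\hat\sigma$ lands on the zero
boundary the fit is flagged `boundary` and fixed-effect standard errors are
computed at $\sigma = 0$.

Fixed-effect conventions:

* Patient clinical risk enters as $\operatorname{logit}(\hat p_{ij})$ with
  an estimated slope — the calibration-slope form — keeping the adjustment
  on the linear-predictor scale. A raw-probability form can be specified
  through `glmm_term(..., "identity")` instead.
* Hospital volume enters linearly, divided by 10, so the reported odds
  ratio is per 10-case annual increase.
* Calendar period enters as 6-level half-year dummies (the trend display is
  the only quarterly analysis).
* Preference enters either as category dummies against the standard
  reference or as the floored continuous score, uncentred: the floor at 1
  already makes "at or below expected use" the reference, so no additional
  centring is applied.
* Confidence intervals are Wald on the log-odds scale at the 0.95 level;
  significance flags never drive model choice.

Subgroup analyses repeat the categorical model within LS-only, open-only,
and annual-volume subgroups split at 20 cases/year (a volume of exactly 20
is high-volume). Subgroups where the contrast is inestimable — no deaths,
an absent category, a failed fit — are reported with a note rather than
raised, since losing one subgroup should not void the others.

The optimizer is `nlminb` over $(\beta, \sigma)$ with $\sigma \ge 0$,
started from the ordinary logistic fit. Near the boundary and with
finite-difference gradients `nlminb`'s own convergence code is
conservative, so convergence is decided by an explicit score check at the
returned optimum (central differences; boundary directions may push
outward). Cross-checks against `lme4::glmer` with the same quadrature
settings agree to about $10^{-5}$ on coefficients and log-likelihood on the
test fixtures.

## Procedures per one excess death

Given an adjusted odds ratio $OR$ (active vs standard preference) and the
standard group's observed operative mortality $p$, the excess risk is
computed through odds space: $o = p/(1-p)$, $p' = OR\,o/(1 + OR\,o)$, and
the procedures-per-one-excess-death count is $\operatorname{round}\{1/(p' -
p)\}$. The baseline is the standard group's *observed* mortality, not a
model-expected value, and rounding is to the nearest integer — the only
combination that reproduces all four published reference figures, which the
acceptance suite recomputes. An $OR \le 1$ yields a flag (infinite or
non-positive excess), never a number.

# The synthetic registry

`sim_config()` fixes the whole data-generating process; its defaults
emulate a distal-gastrectomy-like procedure observed over three years
(12 quarters, 6 half-years):

* **Hospital panel.** 2,000 hospitals with log-normal annual volume
  (median 8 cases/year, log-SD 1.0), mirroring national panels in which
  low-volume centres dominate; a mortality random intercept
  $u_i \sim N(0, 0.3^2)$; and a preference offset $d_i$ drawn from point
  masses $\{-\log 6, 0, +\log 6\}$ with probabilities $\{0.45, 0.49,
  0.06\}$, which yields low/standard/active groups of realistic relative
  size.
* **Patients.** Poisson counts per hospital-year spread uniformly over
  quarters; eight independent covariates (age, sex, emergency, physical
  status, nutrition, respiratory distress, dependence, disseminated
  cancer) drive both mortality risk and the LS choice in opposite
  directions — sicker patients die more and are opened more — which is
  exactly what makes the standardization non-trivial.
* **Outcomes.** LS choice follows
  $\operatorname{expit}(\text{base} + x^\top\gamma + \text{trend}\cdot
  \text{quarter} + d_i)$ with a secular trend of $+0.042$ log-odds per
  quarter (a share rising from roughly 35% to 45%); operative death follows
  the mortality model with an LS effect of $\log 0.8$ and the hospital
  intercept; 30-day death thins operative death with probability 0.6
  (30-day mortality is a subset of operative mortality by definition);
  complication has its own logistic model and no hospital effect, since it
  enters the analyses only descriptively; length of stay is log-normal
  with upward shifts under complication and death and plays no outcome
  role.
* **Determinism.** The seed is mandatory; the panel and patient stages use
  `seed` and `seed + 1`, and an identical configuration reproduces the
  registry file byte for byte. Continuous values are generated at fixed
  decimal precision so the delimited-text round trip is exact.

What the generator does *not* emulate: correlated covariates (a Gaussian
copula could be added, but independence suffices for the analyses tested),
real coding systems or the multi-procedure case mix of national data, and
survival-time outcomes. Passing tests therefore demonstrate that the
*methods* recover planted structure under the stated model; they say
nothing about coding artefacts or confounding patterns specific to real
registries.

# Validation design and problem sizes

The test suite validates each stage against an independent route: closed
forms for null models and Wald intervals; a grid search of the
log-likelihood surface; exhaustive pair enumeration for the concordance
statistic; numerical integration of the chi-square density for the
likelihood-ratio test; `stats::glm` and `lme4::glmer` as independent
implementations; and the score-equation identities for self-fitted models.

Recovery studies use planted effects: an active-preference mortality excess
of 0.6 log-odds with hospital SD 0.3 (the headline condition runs at 200
hospitals and ~50,000 patients; bias and interval coverage are measured
over 200 replicates of 120 hospitals and ~3,300 patients each), and a
volume effect of $-0.10$ per 10 annual cases recovered as the mean of four
replicate registries of ~18,000 patients. Replicated event rates are set
near 10% so each replicate carries enough deaths for maximum-likelihood
asymptotics; recovery configurations zero the LS-on-mortality effect so the
planted group contrast is the estimand rather than a mixture of group and
treatment effects. Stepwise calibration is checked as a type-I entry rate
of about 5% per null candidate over 200 replicates. These sizes are the
package's validation design: large enough that Monte-Carlo error sits well
inside each stated tolerance, small enough to run routinely.

# Known limitations

* The hierarchical model supports a single scalar random intercept — no
  random slopes, crossed effects or survival outcomes.
* Stepwise selection is the field's convention for these propensity
  models and is implemented faithfully, but it inherits stepwise
  selection's known inferential caveats; the pipeline only consumes the
  resulting predicted probabilities, never the selected-model p-values.
* O/E-based profiling is sensitive to small expected counts; the
  `unstable` flag marks, but does not fix, hospitals with tiny
  denominators.
* The impact computation assumes the adjusted odds ratio is transportable
  to the standard-group baseline risk; it is a planning quantity, not a
  causal guarantee.
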