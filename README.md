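# lapref

Hospital profiling of laparoscopic-surgery preference and risk-adjusted
outcomes in multi-hospital surgical registries.

## The problem

Laparoscopic surgery (LS) spread rapidly but unevenly across hospitals:
for the same patient, one centre operates laparoscopically where another
would open. Two questions follow for registry analysts and quality-of-care
researchers:

1. **How strong is each hospital's preference for LS** once its patient
   case mix is accounted for?
2. **Is an unusually strong preference associated with worse
   risk-adjusted operative mortality**, over and above hospital volume and
   patient risk?

`lapref` implements the full pipeline: per-patient logistic risk models
and indirectly standardized observed/expected (O/E) outcome ratios; a
pooled LS-propensity model built by forward stepwise selection (entry
p < 0.05, removal p ≥ 0.10); a hospital **preference score**
O/E = (observed LS count) / (Σ predicted LS probability), categorized as
*active* (O/E ≥ 2), *standard* (0.5 ≤ O/E < 2) or *low* (O/E < 0.5), with
a floored continuous variant max(O/E, 1); random-intercept hierarchical
logistic regression, logit Pr(death) = xᵀβ + uᵢ with uᵢ ~ N(0, σ²),
fitted by adaptive Gauss–Hermite quadrature, for the volume–outcome
(OR per 10-case annual increase) and preference–outcome analyses with
subgroup variants; and the translation of an adjusted odds ratio into
**procedures per one excess operative death**,
round{1 / (p′ − p)} with p′ = OR·o/(1 + OR·o), o = p/(1 − p).

Registries of this kind are access-restricted, so the package includes a
first-class synthetic registry generator (`sim_config()`,
`simulate_registry()`) with planted case mix, hospital preference offsets
and hospital mortality effects, used to validate every stage against known
truth.

## Worked example

```r
library(lapref)

cfg <- sim_config(n_hospitals = 120, volume_median = 10, volume_log_sd = 0.6,
                  mortality_intercept = qlogis(0.03),
                  ls_intercept = qlogis(0.30),
                  pref_offsets = data.frame(offset = c(-log(6), 0, log(6)),
                                            prob = c(0.40, 0.48, 0.12),
                                            mort_log_or = c(0, 0, 0)),
                  seed = 101)
reg <- simulate_registry(cfg)
r <- reg$records            # 4,425 patients in 120 hospitals

risk <- fit_risk_model(r, default_covariates()$name)
risk$c_statistic            # 0.757

head(format_biannual(biannual_table(r, risk)), 4)
#>   half_year scope n_surgery ls_pct observed_mort_pct expected_mort_pct oe_mortality
#> 1         1   all       761  16.2%              7.2%              8.4%         0.86
#> 2         1    ls       123 100.0%              4.1%              5.7%         0.71
#> 3         2   all       753  18.7%              6.9%              8.2%         0.85
#> 4         2    ls       141 100.0%              3.5%              5.7%         0.62

trace <- stepwise_logistic(design_matrix(r, default_covariates()$name),
                           r$ls_flag)
trace$selected
#> [1] "emergency" "age_std" "asa3plus" "albumin_low" "disseminated_cancer"
#> [6] "adl_dependent"

hs <- hospital_preference(r, trace)
table(hs$category)
#>      low standard   active
#>       43       66       11

fit <- preference_outcome_analysis(r, hs, risk, mode = "categorical")
print(fit)
#> Random-intercept logistic fit: 4425 patients in 120 hospitals; 15 quadrature nodes
#> sigma = 0.1182 ; marginal log-likelihood -1105.4463
#>                       term estimate      se     or    low  high
#> 1 expected_mort_logit_risk  1.00417 0.05877 2.7296 2.4327 3.063
#> ...
#> 8              categorylow -0.12956 0.12839 0.8785 0.6830 1.130
#> 9           categoryactive -0.19569 0.22655 0.8223 0.5274 1.282
```

The biannual table mirrors the registry reporting convention (percentages
to 1 decimal, O/E ratios to 2); on a self-fitted risk model the total O/E
is exactly 1, so period values scatter around 1. With no preference-linked
mortality planted (`mort_log_or = c(0, 0, 0)`), the active-vs-standard
odds ratio is compatible with 1, as printed. The expected-mortality term
enters as a calibration slope (estimate ≈ 1 means the risk model is
well calibrated on this registry).

Finally, an adjusted odds ratio becomes a planning quantity:

```r
procedures_per_excess_death(1.83, 0.008)
#> OR 1.83 at baseline 0.8%: risk difference 0.6543% -> 153 procedures per one excess death
```

A thin command-line wrapper (`inst/cli/lapref.R`) exposes
`simulate`, `score` and `report` subcommands over the same functions.

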