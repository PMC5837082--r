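# Shared fixtures: all built in code, cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A moderate registry with planted preference groups, used across modules.
demo_cfg <- function(seed = 101)
  sim_config(
    n_hospitals = 120, volume_median = 10, volume_log_sd = 0.6,
    mortality_intercept = stats::qlogis(0.03),
    ls_intercept = stats::qlogis(0.30),
    pref_offsets = data.frame(offset = c(-log(6), 0, log(6)),
                              prob = c(0.40, 0.48, 0.12),
                              mort_log_or = c(0, 0, 0)),
    seed = seed)

demo_registry <- function() cached("demo_registry", simulate_registry(demo_cfg()))

covariate_names <- function() default_covariates()$name

# Recovery-study configuration: planted active-group mortality log odds
# ratio 0.6 and hospital SD 0.3. Event rate and group sizes are scaled so
# each replicate carries enough deaths and enough active hospitals for
# maximum-likelihood asymptotics; the laparoscopy effect on mortality is
# zero so the planted group contrast is the estimand.
recovery_cfg <- function(seed, n_hospitals = 120, volume_median = 8.3,
                         active_log_or = 0.6, sigma = 0.3)
  sim_config(
    n_hospitals = n_hospitals, volume_median = volume_median,
    volume_log_sd = 0.3,
    mortality_intercept = stats::qlogis(0.045),
    ls_intercept = stats::qlogis(0.25), ls_trend = 0, ls_mort_log_or = 0,
    sigma_mortality = sigma,
    pref_offsets = data.frame(offset = c(-log(9), 0, log(9)),
                              prob = c(0.4, 0.4, 0.2),
                              mort_log_or = c(0, 0, active_log_or)),
    seed = seed)

# One recovery replicate: simulate, refit the risk and propensity models on
# the replicate itself, classify hospitals, fit the preference-outcome
# hierarchical model, return the active-vs-standard estimate and SE.
recovery_replicate <- function(seed, nodes = 9L, ...) {
  reg <- simulate_registry(recovery_cfg(seed, ...))
  r <- reg$records
  rm <- fit_risk_model(r, covariate_names())
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf)
  fit <- preference_outcome_analysis(r, hs, rm, "categorical",
                                     include_period = FALSE,
                                     include_volume = FALSE,
                                     nodes = nodes)
  row <- fit$or_table[fit$or_table$term == "categoryactive", ]
  c(est = row$estimate, se = row$se)
}

# Brute-force concordance: exhaustive enumeration over event/non-event
# pairs, ties counted one half. Independent of the package implementation.
cstat_bruteforce <- function(risk, y) {
  ev <- risk[y == 1]; ne <- risk[y == 0]
  tot <- 0
  for (a in ev) for (b in ne)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}
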