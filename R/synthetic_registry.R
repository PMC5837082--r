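#' Default covariate specification for the synthetic registry
#'
#' A compact case-mix emulating the patient-level factors that drive both
#' operative-mortality risk and the laparoscopic-versus-open choice in
#' gastrointestinal surgery registries: age, sex, emergency presentation,
#' physical-status class, nutritional/laboratory state, respiratory distress,
#' dependence in activities of daily living, and disseminated cancer.
#' Sicker and more urgent patients carry higher mortality risk and are less
#' likely to be offered laparoscopy, which is what makes indirect
#' standardization of laparoscopy use non-trivial.
#'
#' @return a data frame with one row per covariate: `name`, `type`
#'   (`"binary"` or `"continuous"`), `prevalence` (binary), `mean`, `sd`
#'   (continuous), and log odds ratios `mort_log_or`, `ls_log_or`,
#'   `comp_log_or` on mortality, laparoscopy choice and complication.
#' @export
default_covariates <- function() {
  data.frame(
    name = c("age_std", "male", "emergency", "asa3plus", "albumin_low",
             "resp_distress", "adl_dependent", "disseminated_cancer"),
    type = c("continuous", rep("binary", 7L)),
    prevalence = c(NA, 0.60, 0.08, 0.15, 0.20, 0.04, 0.10, 0.05),
    mean = c(0, rep(NA, 7L)),
    sd = c(1, rep(NA, 7L)),
    mort_log_or = c(0.50, 0.10, 1.20, 1.00, 0.70, 0.90, 0.80, 0.80),
    ls_log_or = c(-0.30, -0.10, -1.50, -0.60, -0.40, -0.70, -0.50, -0.80),
    comp_log_or = c(0.30, 0.10, 0.80, 0.60, 0.50, 0.50, 0.40, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a multi-hospital surgical registry
#'
#' Collects every generator parameter: the hospital panel (count, right-skewed
#' log-normal annual-volume distribution, mortality random-intercept SD,
#' laparoscopy-preference offset distribution), the patient case mix, the
#' outcome models (baseline log odds, covariate effects, laparoscopy effect
#' on mortality, secular laparoscopy trend), and the seed. The defaults
#' emulate a distal-gastrectomy-like procedure over three years (12 quarters,
#' 6 half-year periods): roughly 1% operative mortality, a laparoscopy share
#' rising from about 35% to 45%, a hospital panel dominated by low-volume
#' centres (median 8 cases/year, log-SD 1), and a preference-offset mixture
#' whose three point masses generate low/standard/active preference groups of
#' realistic relative size.
#'
#' @param n_hospitals number of hospitals (>= 2).
#' @param procedure procedure label carried into every record.
#' @param years study duration in years; quarters = 4*years, half-years =
#'   2*years.
#' @param volume_median,volume_log_sd log-normal annual-volume parameters
#'   (median on the natural scale, SD on the log scale).
#' @param covariates covariate specification as from [default_covariates()].
#' @param mortality_intercept baseline mortality log odds (covariates at 0).
#' @param ls_intercept baseline laparoscopy log odds at quarter 1.
#' @param ls_mort_log_or additional mortality log odds for laparoscopic cases.
#' @param ls_trend laparoscopy log-odds increment per quarter.
#' @param sigma_mortality SD of the hospital mortality random intercept.
#' @param pref_offsets data frame with columns `offset` (hospital
#'   laparoscopy-preference offset on the log-odds scale), `prob` (mixture
#'   probability, summing to 1) and `mort_log_or` (extra mortality log odds
#'   planted at hospitals drawn from that component; 0 for a null link
#'   between preference and mortality).
#' @param pref_mort_scope whether a planted preference-linked mortality
#'   excess applies to `"all"` cases at the hospital (default) or only to
#'   its `"ls"` cases (used to study subgroup-specific harms).
#' @param death30_prob probability that an operative death occurred within 30
#'   days (30-day deaths are a thinned subset of operative deaths).
#' @param complication_intercept baseline complication log odds.
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters;
#'   complications and deaths shift the location upward.
#' @param seed mandatory integer seed; the whole registry is reproducible
#'   from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_hospitals = 2000L,
                       procedure = "DG",
                       years = 3L,
                       volume_median = 8,
                       volume_log_sd = 1.0,
                       covariates = default_covariates(),
                       mortality_intercept = stats::qlogis(0.006),
                       ls_intercept = stats::qlogis(0.42),
                       ls_mort_log_or = log(0.8),
                       ls_trend = 0.042,
                       sigma_mortality = 0.3,
                       pref_offsets = data.frame(
                         offset = c(-log(6), 0, log(6)),
                         prob = c(0.45, 0.49, 0.06),
                         mort_log_or = c(0, 0, 0)),
                       pref_mort_scope = c("all", "ls"),
                       death30_prob = 0.6,
                       complication_intercept = stats::qlogis(0.10),
                       los_meanlog = log(21),
                       los_sdlog = 0.45,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory in sim_config")
  pref_mort_scope <- match.arg(pref_mort_scope)
  cfg <- list(n_hospitals = as.integer(n_hospitals), procedure = procedure,
              years = as.integer(years), volume_median = volume_median,
              volume_log_sd = volume_log_sd, covariates = covariates,
              mortality_intercept = mortality_intercept,
              ls_intercept = ls_intercept, ls_mort_log_or = ls_mort_log_or,
              ls_trend = ls_trend, sigma_mortality = sigma_mortality,
              pref_offsets = pref_offsets,
              pref_mort_scope = pref_mort_scope,
              death30_prob = death30_prob,
              complication_intercept = complication_intercept,
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_hospitals < 2L) stop("n_hospitals must be >= 2")
  if (cfg$years < 1L) stop("years must be >= 1")
  if (cfg$sigma_mortality < 0) stop("sigma_mortality must be >= 0")
  if (cfg$volume_median <= 0 || cfg$volume_log_sd < 0)
    stop("invalid volume distribution parameters")
  cv <- cfg$covariates
  need <- c("name", "type", "prevalence", "mean", "sd",
            "mort_log_or", "ls_log_or", "comp_log_or")
  if (!all(need %in% names(cv)))
    stop("covariate spec lacks columns: ",
         paste(setdiff(need, names(cv)), collapse = ", "))
  bin <- cv$type == "binary"
  if (any(!is.finite(cv$prevalence[bin]) |
          cv$prevalence[bin] <= 0 | cv$prevalence[bin] >= 1))
    stop("binary covariate prevalences must lie in (0, 1)")
  po <- cfg$pref_offsets
  if (abs(sum(po$prob) - 1) > 1e-8)
    stop("pref_offsets probabilities must sum to 1")
  if (any(po$prob < 0)) stop("pref_offsets probabilities must be >= 0")
  if (cfg$death30_prob < 0 || cfg$death30_prob > 1)
    stop("death30_prob must lie in [0, 1]")
  invisible(cfg)
}

#' Generate the hospital panel
#'
#' Draws, reproducibly from the configuration seed, each hospital's expected
#' annual volume (log-normal, rounded up to at least one case), mortality
#' random intercept `u ~ Normal(0, sigma_mortality^2)`, and
#' laparoscopy-preference offset `d` (with any planted preference-linked
#' mortality effect) from the configured mixture.
#'
#' @param cfg a [sim_config()].
#' @return data frame: `hospital_id`, `annual_volume`, `u_mort`, `d_pref`,
#'   `pref_mort_log_or`, `pref_component` (mixture component index).
#' @export
generate_hospitals <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_hospitals
  vol <- pmax(1, ceiling(stats::rlnorm(m, meanlog = log(cfg$volume_median),
                                       sdlog = cfg$volume_log_sd)))
  u <- if (cfg$sigma_mortality > 0)
    stats::rnorm(m, 0, cfg$sigma_mortality) else rep(0, m)
  comp <- sample.int(nrow(cfg$pref_offsets), m, replace = TRUE,
                     prob = cfg$pref_offsets$prob)
  data.frame(
    hospital_id = sprintf("H%04d", seq_len(m)),
    annual_volume = as.numeric(vol),
    u_mort = u,
    d_pref = cfg$pref_offsets$offset[comp],
    pref_mort_log_or = cfg$pref_offsets$mort_log_or[comp],
    pref_component = comp,
    stringsAsFactors = FALSE
  )
}

#' Generate patient records for a hospital panel
#'
#' Patient counts are Poisson with mean `annual_volume * years`, allocated
#' uniformly over quarters. Covariates are independent draws from the
#' configured case mix (continuous values rounded to 4 decimals so that the
#' delimited-text registry round-trips exactly). The laparoscopy flag follows
#' a logistic model combining case mix, the secular trend and the hospital
#' preference offset; operative death follows a logistic model combining
#' case mix, the laparoscopy effect, the hospital random intercept and any
#' planted preference-linked excess; 30-day death is a thinned subset of
#' operative death; complication has its own logistic model. Uses the
#' stream seeded by `cfg$seed + 1` so the panel and patient stages are
#' independently reproducible.
#'
#' @param cfg a [sim_config()].
#' @param hospitals a panel from [generate_hospitals()] (possibly modified to
#'   plant bespoke designs).
#' @return data frame of patient records in canonical registry column order.
#' @export
generate_patients <- function(cfg, hospitals) {
  validate_sim_config(cfg)
  if (!is.data.frame(hospitals) || nrow(hospitals) == 0L)
    stop("hospital table is empty")
  set.seed(cfg$seed + 1L)
  m <- nrow(hospitals)
  n_q <- 4L * cfg$years
  counts <- stats::rpois(m, hospitals$annual_volume * cfg$years)
  g <- rep.int(seq_len(m), counts)
  n <- length(g)
  if (n == 0L) stop("no patients generated; volumes too small")
  quarter <- sample.int(n_q, n, replace = TRUE)

  cv <- cfg$covariates
  X <- matrix(0, n, nrow(cv), dimnames = list(NULL, cv$name))
  for (j in seq_len(nrow(cv))) {
    X[, j] <- if (cv$type[j] == "binary")
      stats::rbinom(n, 1L, cv$prevalence[j])
    else round(stats::rnorm(n, cv$mean[j], cv$sd[j]), 4L)
  }

  eta_ls <- cfg$ls_intercept + drop(X %*% cv$ls_log_or) +
    cfg$ls_trend * (quarter - 1) + hospitals$d_pref[g]
  ls_flag <- stats::rbinom(n, 1L, stats::plogis(eta_ls))

  pref_excess <- hospitals$pref_mort_log_or[g]
  if (cfg$pref_mort_scope == "ls") pref_excess <- pref_excess * ls_flag
  eta_mort <- cfg$mortality_intercept + drop(X %*% cv$mort_log_or) +
    ls_flag * cfg$ls_mort_log_or + hospitals$u_mort[g] + pref_excess
  operative_death <- stats::rbinom(n, 1L, stats::plogis(eta_mort))
  death30 <- operative_death * stats::rbinom(n, 1L, cfg$death30_prob)

  eta_comp <- cfg$complication_intercept + drop(X %*% cv$comp_log_or)
  complication <- stats::rbinom(n, 1L, stats::plogis(eta_comp))

  los <- round(stats::rlnorm(n, cfg$los_meanlog + 0.3 * complication +
                               0.2 * operative_death, cfg$los_sdlog), 1L)

  out <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    hospital_id = hospitals$hospital_id[g],
    procedure = cfg$procedure,
    quarter = quarter,
    half_year = (quarter + 1L) %/% 2L,
    ls_flag = ls_flag,
    death30 = death30,
    operative_death = operative_death,
    complication = complication,
    length_of_stay = los,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(X))
}

#' Simulate a complete registry
#'
#' Convenience wrapper running [generate_hospitals()] then
#' [generate_patients()].
#'
#' @param cfg a [sim_config()].
#' @return list with elements `hospitals` and `records`.
#' @export
simulate_registry <- function(cfg) {
  hospitals <- generate_hospitals(cfg)
  list(hospitals = hospitals, records = generate_patients(cfg, hospitals))
}

registry_required_columns <- c(
  "patient_id", "hospital_id", "procedure", "quarter", "half_year",
  "ls_flag", "death30", "operative_death", "length_of_stay")

#' Write / read a registry as delimited text
#'
#' The registry file is comma-delimited with a header row: the canonical
#' identifier, period, treatment and outcome columns first, then the
#' covariate columns. `read_registry` enforces the registry contract:
#' every mandatory column present, no missing values in any mandatory
#' column (the error names the offending column), 30-day death a subset of
#' operative death, and half-year consistent with quarter.
#'
#' @param records a patient record data frame.
#' @param path file path.
#' @return `read_registry` returns the validated data frame;
#'   `write_registry` returns `path` invisibly.
#' @export
write_registry <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (nrow(records) > 0L) {
    miss <- setdiff(registry_required_columns, names(records))
    if (length(miss))
      stop("records lack mandatory columns: ", paste(miss, collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(registry_required_columns, names(records))
  if (length(miss))
    stop("registry file lacks mandatory columns: ",
         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(records)
  for (col in registry_required_columns) {
    v <- records[[col]]
    if (anyNA(v) || (is.character(v) && any(!nzchar(v))))
      stop("missing values in mandatory column: ", col)
  }
  if (any(records$death30 > records$operative_death))
    stop("invalid registry: death30 = 1 with operative_death = 0")
  if (any(records$half_year != (records$quarter + 1L) %/% 2L))
    stop("invalid registry: half_year inconsistent with quarter")
  records
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$covariates <- lapply(seq_len(nrow(cfg$covariates)), function(i)
    as.list(cfg$covariates[i, ]))
  x$pref_offsets <- lapply(seq_len(nrow(cfg$pref_offsets)), function(i)
    as.list(cfg$pref_offsets[i, ]))
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$covariates <- do.call(rbind, lapply(x$covariates, function(r)
    data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
               stringsAsFactors = FALSE)))
  x$pref_offsets <- do.call(rbind, lapply(x$pref_offsets, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  do.call(sim_config, x)
}
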