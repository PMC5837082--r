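#' Construct a logistic risk model
#'
#' A risk model is a named coefficient vector plus intercept on the log-odds
#' scale, applied to registry covariates to produce each patient's expected
#' probability of an outcome (operative death or complication). Models may be
#' loaded from configuration (externally published coefficients) or refitted
#' on a registry with [fit_risk_model()].
#'
#' @param outcome outcome column name (`"operative_death"` or
#'   `"complication"`).
#' @param intercept intercept on the log-odds scale.
#' @param coefficients named numeric vector of covariate log odds ratios
#'   (may be empty for an intercept-only model).
#' @param procedure optional procedure label.
#' @param note provenance note (where the coefficients come from).
#' @param c_statistic optional discrimination of the model, in `[0, 1]`.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(outcome, intercept, coefficients = numeric(),
                       procedure = "", note = "", c_statistic = NA_real_) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by covariate")
  if (!is.na(c_statistic) && (c_statistic < 0 || c_statistic > 1))
    stop("c_statistic must lie in [0, 1]")
  structure(list(outcome = outcome, intercept = intercept,
                 coefficients = coefficients, procedure = procedure,
                 note = note, c_statistic = c_statistic),
            class = "risk_model")
}

#' Fit a risk model on registry records
#'
#' Convenience wrapper around [fit_logistic()] returning a [risk_model()]
#' whose expected risks are calibrated to the fitting registry (total
#' observed/expected ratio exactly 1, a consequence of the logistic score
#' equations).
#'
#' @param records registry data frame.
#' @param covariates character vector of covariate column names.
#' @param outcome outcome column name.
#' @param procedure optional procedure label.
#' @return a `risk_model` with fit-derived `c_statistic`.
#' @export
fit_risk_model <- function(records, covariates,
                           outcome = "operative_death", procedure = "") {
  X <- design_matrix(records, covariates)
  fit <- fit_logistic(X, records[[outcome]])
  risk_model(outcome = outcome,
             intercept = fit$coefficients[["(Intercept)"]],
             coefficients = fit$coefficients[-1L],
             procedure = procedure,
             note = "fitted on supplied registry",
             c_statistic = fit$c_statistic)
}

#' Expected outcome risk for registry records
#'
#' Evaluates `expit(intercept + sum(coefficient * covariate))` per record.
#'
#' @param model a [risk_model()].
#' @param records registry data frame containing every model covariate.
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
expected_risk <- function(model, records) {
  stopifnot(inherits(model, "risk_model"))
  miss <- setdiff(names(model$coefficients), names(records))
  if (length(miss))
    stop("records lack model covariates: ", paste(miss, collapse = ", "))
  eta <- rep(model$intercept, nrow(records))
  for (nm in names(model$coefficients)) {
    v <- records[[nm]]
    if (anyNA(v)) stop("missing values in covariate: ", nm)
    eta <- eta + model$coefficients[[nm]] * v
  }
  stats::plogis(eta)
}

#' Observed/expected ratio
#'
#' The indirect-standardization statistic used throughout hospital
#' profiling: observed events (or an observed rate) divided by the
#' model-expected events (or expected rate). Scale-free: counts and rates on
#' a common denominator give the same ratio.
#'
#' @param observed observed event count or rate (>= 0).
#' @param expected expected event count or rate (> 0).
#' @return the ratio `observed/expected`.
#' @export
oe_ratio <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected must be positive; O/E undefined otherwise")
  if (any(observed < 0)) stop("observed must be >= 0")
  observed / expected
}

#' Biannual descriptive table of surgery counts, mortality and O/E ratios
#'
#' For each procedure and half-year period, tabulates — for all surgeries and
#' for the laparoscopic subset — the number of operations, the laparoscopy
#' proportion, observed and model-expected operative mortality, the O/E
#' mortality ratio, 30-day mortality, and (when a complication model is
#' supplied and the registry carries a `complication` column) observed and
#' expected complication rates with their O/E ratio. Percentages are kept at
#' full precision; display rounding (1 decimal for percentages, 2 for O/E
#' ratios) is applied by [format_biannual()].
#'
#' Periods whose expected-event sum is zero get `NA` O/E cells (undefined
#' standardization), never zero.
#'
#' @param records registry data frame.
#' @param mortality_model a [risk_model()] for operative death, or `NULL`
#'   to produce observed-only columns.
#' @param complication_model optional [risk_model()] for complication.
#' @return a data frame with one row per procedure x half-year x scope
#'   (`"all"` or `"ls"`).
#' @export
biannual_table <- function(records, mortality_model = NULL,
                           complication_model = NULL) {
  if (nrow(records) == 0L) stop("no records")
  exp_mort <- if (!is.null(mortality_model))
    expected_risk(mortality_model, records) else rep(NA_real_, nrow(records))
  exp_comp <- if (!is.null(complication_model) &&
                  "complication" %in% names(records))
    expected_risk(complication_model, records) else rep(NA_real_, nrow(records))

  one_cell <- function(idx, scope) {
    r <- records[idx, , drop = FALSE]
    n <- nrow(r)
    em <- exp_mort[idx]; ec <- exp_comp[idx]
    exp_mort_sum <- if (all(is.na(em))) NA_real_ else sum(em)
    exp_comp_sum <- if (all(is.na(ec))) NA_real_ else sum(ec)
    obs_mort <- sum(r$operative_death)
    obs_comp <- if ("complication" %in% names(r)) sum(r$complication) else NA_real_
    data.frame(
      procedure = r$procedure[1L], half_year = r$half_year[1L],
      scope = scope, n_surgery = n, n_ls = sum(r$ls_flag),
      ls_pct = 100 * mean(r$ls_flag),
      mort30_pct = 100 * mean(r$death30),
      observed_mort_pct = 100 * obs_mort / n,
      expected_mort_pct = 100 * exp_mort_sum / n,
      oe_mortality = if (is.na(exp_mort_sum) || exp_mort_sum == 0) NA_real_
        else obs_mort / exp_mort_sum,
      observed_comp_pct = 100 * obs_comp / n,
      expected_comp_pct = 100 * exp_comp_sum / n,
      oe_complication = if (is.na(exp_comp_sum) || exp_comp_sum == 0 ||
                            is.na(obs_comp)) NA_real_
        else obs_comp / exp_comp_sum,
      stringsAsFactors = FALSE)
  }

  key <- interaction(records$procedure, records$half_year, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    all_row <- one_cell(idx, "all")
    ls_idx <- idx[records$ls_flag[idx] == 1]
    if (length(ls_idx)) rbind(all_row, one_cell(ls_idx, "ls")) else all_row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$procedure, out$half_year, out$scope), ]
  rownames(out) <- NULL
  out
}

#' Display formatting for the biannual table
#'
#' Applies the reporting convention: percentages to 1 decimal, O/E ratios to
#' 2 decimals; undefined O/E cells print as `"--"`.
#'
#' @param tab output of [biannual_table()].
#' @return a character-formatted data frame for printing/export.
#' @export
format_biannual <- function(tab) {
  out <- tab
  pct <- grep("_pct$", names(out), value = TRUE)
  for (col in pct)
    out[[col]] <- ifelse(is.na(tab[[col]]), "--",
                         sprintf("%.1f%%", tab[[col]]))
  for (col in c("oe_mortality", "oe_complication"))
    out[[col]] <- ifelse(is.na(tab[[col]]), "--", sprintf("%.2f", tab[[col]]))
  out
}

#' Quarterly laparoscopy-proportion trend
#'
#' @param records registry data frame with populated `quarter`.
#' @return data frame `procedure`, `quarter`, `n`, `n_ls`, `ls_pct`
#'   (percentage in `[0, 100]`); quarters with no records are absent.
#' @export
quarterly_ls_trend <- function(records) {
  key <- interaction(records$procedure, records$quarter, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    data.frame(procedure = records$procedure[idx[1L]],
               quarter = records$quarter[idx[1L]],
               n = length(idx), n_ls = sum(records$ls_flag[idx]),
               ls_pct = 100 * mean(records$ls_flag[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$procedure, out$quarter), ]
  rownames(out) <- NULL
  out
}

#' Write / read a risk model as YAML
#'
#' @param model a [risk_model()].
#' @param path file path.
#' @return `read_risk_model` returns a `risk_model`; `write_risk_model`
#'   returns `path` invisibly.
#' @export
write_risk_model <- function(model, path) {
  yaml::write_yaml(list(
    outcome = model$outcome, procedure = model$procedure,
    intercept = model$intercept, note = model$note,
    c_statistic = if (is.na(model$c_statistic)) NULL else model$c_statistic,
    coefficients = as.list(model$coefficients)), path)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- yaml::read_yaml(path)
  risk_model(outcome = x$outcome, intercept = x$intercept,
             coefficients = unlist(x$coefficients),
             procedure = if (is.null(x$procedure)) "" else x$procedure,
             note = if (is.null(x$note)) "" else x$note,
             c_statistic = if (is.null(x$c_statistic)) NA_real_
               else x$c_statistic)
}
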