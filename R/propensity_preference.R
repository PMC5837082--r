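#' Forward stepwise logistic regression with likelihood-ratio entry/exit
#'
#' Builds the laparoscopy-propensity model by forward selection with
#' backward pruning: at each round the excluded candidate with the smallest
#' likelihood-ratio p-value enters if it is below `p_enter`; included
#' columns are then re-tested and any with p at or above `p_exit` is removed
#' (largest p first). Ties in p-value are broken by the larger test
#' statistic, then by column-name order, so the procedure is deterministic
#' given the data. Candidates whose trial fit fails (e.g. separation) are
#' skipped with a warning. A cycle guard raises an error if a previously
#' visited model state recurs.
#'
#' @param X a [design_matrix()] containing the intercept and all candidate
#'   columns.
#' @param y binary treatment indicator (1 = laparoscopic).
#' @param p_enter entry threshold (default 0.05).
#' @param p_exit exit threshold (default 0.10); must exceed `p_enter`.
#' @param max_steps safety bound on total steps.
#' @return object of class `stepwise_trace`: `steps` (data frame: action,
#'   column, statistic, p_value), `selected` (final column set), `fit`
#'   (final converged [fit_logistic()] on intercept + selected columns).
#' @export
stepwise_logistic <- function(X, y, p_enter = 0.05, p_exit = 0.10,
                              max_steps = 200L) {
  X <- unclass(X)
  if (p_exit < p_enter) stop("p_exit must be >= p_enter")
  candidates <- setdiff(colnames(X), "(Intercept)")
  selected <- character()
  steps <- list()
  seen <- character()
  fit_cols <- function(cols)
    fit_logistic(X[, c("(Intercept)", cols), drop = FALSE], y)
  current <- fit_cols(selected)

  repeat {
    if (length(steps) >= max_steps)
      stop("stepwise selection exceeded ", max_steps, " steps")
    changed <- FALSE

    # entry: best remaining candidate
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      trial <- lapply(pool, function(col) {
        tryCatch({
          f <- fit_cols(c(selected, col))
          t <- lr_test(f, current, df = 1L)
          list(col = col, fit = f, stat = t$statistic, p = t$p_value)
        }, error = function(e) {
          warning("candidate ", col, " skipped: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      })
      trial <- Filter(Negate(is.null), trial)
      if (length(trial)) {
        p <- vapply(trial, `[[`, numeric(1), "p")
        stat <- vapply(trial, `[[`, numeric(1), "stat")
        col <- vapply(trial, `[[`, character(1), "col")
        ord <- order(p, -stat, col)
        best <- trial[[ord[1L]]]
        if (best$p < p_enter) {
          selected <- c(selected, best$col)
          current <- best$fit
          steps[[length(steps) + 1L]] <- data.frame(
            action = "enter", column = best$col, statistic = best$stat,
            p_value = best$p, stringsAsFactors = FALSE)
          changed <- TRUE
        }
      }
    }

    # exit: re-test included columns, drop worst offenders one at a time
    repeat {
      if (!length(selected)) break
      tests <- lapply(selected, function(col) {
        f <- fit_cols(setdiff(selected, col))
        t <- lr_test(current, f, df = 1L)
        list(col = col, stat = t$statistic, p = t$p_value)
      })
      p <- vapply(tests, `[[`, numeric(1), "p")
      stat <- vapply(tests, `[[`, numeric(1), "stat")
      col <- vapply(tests, `[[`, character(1), "col")
      ord <- order(-p, stat, col)
      worst <- tests[[ord[1L]]]
      if (worst$p < p_exit) break
      selected <- setdiff(selected, worst$col)
      current <- fit_cols(selected)
      steps[[length(steps) + 1L]] <- data.frame(
        action = "remove", column = worst$col, statistic = worst$stat,
        p_value = worst$p, stringsAsFactors = FALSE)
      changed <- TRUE
    }

    if (!changed) break
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen)
      stop("stepwise selection oscillated: model state revisited")
    seen <- c(seen, state)
  }

  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(action = character(), column = character(),
                 statistic = numeric(), p_value = numeric(),
                 stringsAsFactors = FALSE),
    selected = selected,
    fit = current
  ), class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Stepwise logistic selection:", length(x$selected),
      "columns retained\n")
  if (nrow(x$steps)) print(x$steps, digits = 4) else cat("  (no steps)\n")
  invisible(x)
}

#' Expected laparoscopy count for a set of records
#'
#' Sums the predicted laparoscopy probabilities from a pooled propensity
#' model over the records of one hospital — the denominator of the
#' preference score.
#'
#' @param fit a converged propensity fit ([fit_logistic()] or the `fit` of a
#'   [stepwise_logistic()] trace).
#' @param records the hospital's registry records.
#' @return the real-valued expected count.
#' @export
expected_ls_count <- function(fit, records) {
  if (inherits(fit, "stepwise_trace")) fit <- fit$fit
  if (isFALSE(fit$converged)) stop("propensity fit did not converge")
  if (nrow(records) == 0L) stop("no records supplied")
  covs <- setdiff(names(fit$coefficients), "(Intercept)")
  miss <- setdiff(covs, names(records))
  if (length(miss))
    stop("records lack propensity covariates: ", paste(miss, collapse = ", "))
  X <- design_matrix(records, covs)
  sum(stats::plogis(drop(X %*% fit$coefficients)))
}

#' Hospital preference score, category and floored transform
#'
#' The preference score is the hospital's observed/expected ratio for the
#' number of laparoscopic procedures. Categories use half-open thresholds:
#' active iff score >= 2, standard iff 0.5 <= score < 2, low iff
#' score < 0.5. The floored transform `max(score, 1)` treats hospitals at or
#' below expected use as the reference in continuous-score models.
#'
#' @param observed_ls observed laparoscopy count (>= 0).
#' @param expected_ls expected laparoscopy count; must be positive, else the
#'   score is undefined and the hospital is excluded from preference
#'   analyses.
#' @return list with `score`, `category` (factor low/standard/active) and
#'   `floored`.
#' @export
preference_score <- function(observed_ls, expected_ls) {
  if (any(expected_ls <= 0))
    stop("expected_ls must be positive; preference score undefined")
  if (any(observed_ls < 0)) stop("observed_ls must be >= 0")
  score <- observed_ls / expected_ls
  category <- preference_category(score)
  list(score = score, category = category, floored = pmax(score, 1))
}

preference_category <- function(score) {
  factor(ifelse(score >= 2, "active", ifelse(score >= 0.5, "standard", "low")),
         levels = c("low", "standard", "active"))
}

#' Per-hospital preference summary
#'
#' Aggregates a registry to one row per hospital: volume (mean annual over
#' the study period), observed and expected laparoscopy counts, the
#' preference score with its category and floored transform, observed
#' operative mortality and mean length of stay. Hospitals with expected
#' laparoscopy count below `min_expected` are flagged `unstable` (ratio
#' estimators explode at tiny denominators) but retained.
#'
#' @param records registry data frame.
#' @param propensity a converged propensity fit or [stepwise_logistic()]
#'   trace, pooled over all hospitals.
#' @param years study duration used to annualize volume (default 3).
#' @param min_expected stability floor for the expected count (default 0.5).
#' @return data frame of class `hospital_summary`, one row per hospital.
#' @export
hospital_preference <- function(records, propensity, years = 3,
                                min_expected = 0.5) {
  if (inherits(propensity, "stepwise_trace")) propensity <- propensity$fit
  covs <- setdiff(names(propensity$coefficients), "(Intercept)")
  miss <- setdiff(covs, names(records))
  if (length(miss))
    stop("records lack propensity covariates: ", paste(miss, collapse = ", "))
  X <- design_matrix(records, covs)
  p_ls <- stats::plogis(drop(X %*% propensity$coefficients))

  idx <- split(seq_len(nrow(records)), records$hospital_id)
  rows <- lapply(idx, function(i) {
    expected <- sum(p_ls[i])
    observed <- sum(records$ls_flag[i])
    score <- if (expected > 0) observed / expected else NA_real_
    data.frame(
      hospital_id = records$hospital_id[i[1L]],
      procedure = records$procedure[i[1L]],
      n_patients = length(i),
      n_ls = observed,
      expected_ls = expected,
      score = score,
      category = preference_category(score),
      floored = pmax(score, 1),
      annual_volume = length(i) / years,
      observed_mortality_pct = 100 * mean(records$operative_death[i]),
      mean_los = mean(records$length_of_stay[i]),
      unstable = expected < min_expected,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hospital_summary", class(out))
  out
}

#' Descriptive statistics by preference category
#'
#' One row per preference category: hospital and patient counts, median
#' (IQR) annual volume across hospitals, mean and SD length of stay across
#' patients, and observed operative mortality. Quantiles use linear
#' interpolation (R type 7), recorded in the `quantile_type` attribute.
#' Empty categories yield zero-count rows.
#'
#' @param summaries a [hospital_preference()] table.
#' @param records the matching registry data frame.
#' @return data frame with one row per category (low, standard, active).
#' @export
preference_group_descriptives <- function(summaries, records) {
  cat_by_hosp <- stats::setNames(as.character(summaries$category),
                                 summaries$hospital_id)
  rec_cat <- cat_by_hosp[records$hospital_id]
  rows <- lapply(levels(summaries$category), function(cl) {
    h <- summaries[!is.na(summaries$category) & summaries$category == cl, ]
    r <- records[!is.na(rec_cat) & rec_cat == cl, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(category = cl, n_hospitals = 0L, n_patients = 0L,
                        volume_median = NA_real_, volume_q1 = NA_real_,
                        volume_q3 = NA_real_, los_mean = NA_real_,
                        los_sd = NA_real_, mortality_pct = NA_real_,
                        stringsAsFactors = FALSE))
    q <- stats::quantile(h$annual_volume, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(category = cl, n_hospitals = nrow(h), n_patients = nrow(r),
               volume_median = q[2L], volume_q1 = q[1L], volume_q3 = q[3L],
               los_mean = mean(r$length_of_stay),
               los_sd = stats::sd(r$length_of_stay),
               mortality_pct = 100 * mean(r$operative_death),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "quantile_type") <- 7L
  out
}
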