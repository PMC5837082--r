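#' Build a design matrix with an explicit intercept
#'
#' Assembles the covariate columns of a logistic model (risk model or
#' laparoscopy-propensity model) into a validated numeric matrix whose first
#' column is an explicit intercept. All downstream fitting functions in the
#' package consume this representation.
#'
#' @param data a data frame holding the covariate columns.
#' @param columns character vector of column names to include (may be empty
#'   for an intercept-only design). Each must be numeric (0/1 for binary
#'   covariates) and free of missing values.
#' @param row_ids optional character/integer vector of row identifiers
#'   (e.g. patient ids); defaults to the row names of `data`.
#'
#' @return a numeric matrix of class `design_matrix` with unique column
#'   names, first column `(Intercept)`.
#' @export
design_matrix <- function(data, columns = character(), row_ids = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("design matrix needs at least one row")
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(columns))
    stop("duplicate column names: ",
         paste(unique(columns[duplicated(columns)]), collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(columns)) {
    vals <- as.matrix(data[columns])
    if (!is.numeric(vals)) stop("all covariate columns must be numeric")
    X <- cbind(X, vals)
  }
  if (anyNA(X)) {
    bad <- colnames(X)[apply(X, 2L, anyNA)]
    stop("missing values in design columns: ", paste(bad, collapse = ", "))
  }
  rownames(X) <- if (is.null(row_ids)) rownames(data) else as.character(row_ids)
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Reference maximum-likelihood fitter used by every modelling stage of the
#' package: patient risk models, laparoscopy-propensity models and the fixed
#' start of the hierarchical outcome models. Convergence requires both a
#' score (gradient) max-norm at most `tol_grad` and a relative log-likelihood
#' change at most `tol_ll`; steps that would decrease the likelihood are
#' halved. Complete or quasi-complete separation is detected through a
#' diverging coefficient norm and raised as an error rather than silently
#' penalized, because the profiling analyses assume plain maximum-likelihood
#' models.
#'
#' @param X a [design_matrix()] (or numeric matrix whose first column is an
#'   intercept).
#' @param y binary 0/1 outcome vector aligned with the rows of `X`; both
#'   classes must be present.
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol_grad convergence tolerance on the score max-norm.
#' @param tol_ll convergence tolerance on the relative log-likelihood change.
#'
#' @return an object of class `logistic_fit`: list with `coefficients`,
#'   `vcov` (inverse observed Fisher information), `loglik`, `fitted`
#'   (probabilities), `c_statistic`, `converged`, `iterations`, `n`,
#'   `n_events`.
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol_grad = 1e-8,
                         tol_ll = 1e-10) {
  X <- unclass(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; a logistic model is not identifiable")
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  ll <- bernoulli_loglik(y, eta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu))
    # Newton step through the weighted least-squares normal equations
    XtWX <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(XtWX, grad), error = function(e)
      stop("information matrix singular during IRLS (columns: ",
           paste(colnames(X), collapse = ", "), ")"))
    halvings <- 0L
    repeat {
      beta_new <- beta + step
      eta_new <- drop(X %*% beta_new)
      ll_new <- bernoulli_loglik(y, eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      halvings <- halvings + 1L
      if (halvings > 30L)
        stop("IRLS step-halving failed to increase the likelihood")
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    if (max(abs(beta)) > 30)
      stop("coefficients diverging (|beta| > 30 on the log-odds scale); ",
           "data are separated for columns: ",
           paste(colnames(X)[abs(beta) > 30], collapse = ", "))
    grad <- drop(crossprod(X, y - stats::plogis(eta)))
    if (max(abs(grad)) <= tol_grad && rel_change <= tol_ll) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("IRLS failed to converge after ", max_iter,
         " iterations (columns: ", paste(colnames(X), collapse = ", "), ")")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    vcov = vcov,
    loglik = ll,
    fitted = mu,
    c_statistic = c_statistic(mu, y),
    converged = converged,
    iterations = iter,
    n = length(y),
    n_events = sum(y)
  ), class = "logistic_fit")
}

bernoulli_loglik <- function(y, eta) {
  # numerically stable: -log(1+exp(-eta)) for y=1, -log(1+exp(eta)) for y=0
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$n, "rows,", x$n_events, "events;",
      "log-likelihood", format(x$loglik, digits = 6),
      "; c-statistic", format(x$c_statistic, digits = 3), "\n")
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, se = se), digits = 4)
  invisible(x)
}

#' Concordance (c-) statistic
#'
#' Probability that a randomly chosen event receives a higher predicted risk
#' than a randomly chosen non-event, counting ties as one half
#' (Mann-Whitney convention); equal to the area under the ROC curve.
#'
#' @param risk predicted probabilities (or any risk score) in `[0, 1]`.
#' @param y binary 0/1 outcome vector; both classes must be present.
#' @return the concordance probability in `[0, 1]`.
#' @export
c_statistic <- function(risk, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("y contains a single class; c-statistic undefined")
  if (anyNA(risk)) stop("missing values in risk")
  # midranks give the tie-as-half Mann-Whitney count
  r <- rank(risk, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Odds ratio with Wald confidence interval
#'
#' @param fit a converged [fit_logistic()] result.
#' @param column coefficient name.
#' @param level confidence level (default 0.95).
#' @return a list with `or`, `low`, `high`, `se`, and `degenerate` (TRUE when
#'   the standard error is zero, in which case the interval carries no
#'   uncertainty and must not be interpreted as a Wald interval).
#' @export
wald_or_ci <- function(fit, column, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit") || is.list(fit))
  if (isFALSE(fit$converged)) stop("fit did not converge; inference invalid")
  if (!column %in% names(fit$coefficients))
    stop("unknown coefficient: ", column)
  beta <- fit$coefficients[[column]]
  se <- sqrt(fit$vcov[column, column])
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(or = exp(beta), low = exp(beta - z * se),
              high = exp(beta + z * se), se = se, degenerate = se == 0)
  if (out$degenerate)
    warning("zero standard error for ", column,
            ": confidence interval is degenerate")
  out
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced converged [fit_logistic()] results; the reduced
#'   model's columns must be a subset of the full model's.
#' @param df degrees of freedom; defaults to the difference in the number of
#'   coefficients.
#' @return list with `statistic` (twice the log-likelihood difference,
#'   floored at 0 within tolerance), `df`, `p_value`.
#' @export
lr_test <- function(full, reduced, df = NULL) {
  if (isFALSE(full$converged) || isFALSE(reduced$converged))
    stop("both fits must have converged")
  extra <- setdiff(names(reduced$coefficients), names(full$coefficients))
  if (length(extra))
    stop("models are not nested; reduced-only columns: ",
         paste(extra, collapse = ", "))
  if (is.null(df))
    df <- length(full$coefficients) - length(reduced$coefficients)
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("full-model log-likelihood below reduced model's: a fit failed")
  stat <- max(stat, 0)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}
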