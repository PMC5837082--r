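#' Fixed-effect term of a hierarchical outcome model
#'
#' @param column source column in the registry (or a derived column added by
#'   an analysis wrapper).
#' @param transform one of `"identity"`, `"per10"` (column divided by 10,
#'   used for hospital volume so the odds ratio is reported per 10-case
#'   increase), `"logit_risk"` (logit of a model-expected risk, the
#'   calibration-slope form of patient-level risk adjustment) or
#'   `"dummies"` (indicator columns for a categorical term).
#' @param reference reference level for `"dummies"` (mandatory for that
#'   transform).
#' @return a `glmm_term` list.
#' @export
glmm_term <- function(column,
                      transform = c("identity", "per10", "logit_risk",
                                    "dummies"),
                      reference = NULL) {
  transform <- match.arg(transform)
  if (transform == "dummies" && is.null(reference))
    stop("dummies terms need an explicit reference level")
  structure(list(column = column, transform = transform,
                 reference = reference), class = "glmm_term")
}

#' Specification of a random-intercept logistic model
#'
#' @param outcome binary outcome column.
#' @param terms list of [glmm_term()]s.
#' @param group grouping column (hospital id); must have at least two
#'   levels.
#' @param nodes adaptive Gauss-Hermite quadrature nodes (default 15; 1 gives
#'   the Laplace approximation).
#' @return a `glmm_spec` list.
#' @export
glmm_spec <- function(outcome, terms, group = "hospital_id", nodes = 15L) {
  stopifnot(is.list(terms), all(vapply(terms, inherits, TRUE, "glmm_term")))
  if (nodes < 1L) stop("nodes must be >= 1")
  structure(list(outcome = outcome, terms = terms, group = group,
                 nodes = as.integer(nodes)), class = "glmm_spec")
}

# Build the fixed-effect design matrix for a glmm_spec. Zero-variance
# dummy columns (categories absent from the data) are dropped with a
# warning; any other constant column is an error (degenerate term).
build_glmm_design <- function(records, spec) {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  for (tm in spec$terms) {
    v <- records[[tm$column]]
    if (is.null(v)) stop("term column not found: ", tm$column)
    if (tm$transform == "dummies") {
      f <- as.factor(v)
      lv <- levels(f)
      if (!tm$reference %in% lv)
        stop("reference level '", tm$reference, "' absent from ", tm$column)
      for (l in setdiff(lv, tm$reference)) {
        d <- as.numeric(f == l)
        if (stats::var(d) == 0) {
          if (sum(d) == 0)
            warning("category '", l, "' of ", tm$column,
                    " absent from the data; contrast omitted")
          else stop("degenerate term: ", tm$column, " has a single level")
          next
        }
        cols[[paste0(tm$column, l)]] <- d
      }
    } else {
      if (anyNA(v)) stop("missing values in term column: ", tm$column)
      x <- switch(tm$transform,
                  identity = as.numeric(v),
                  per10 = as.numeric(v) / 10,
                  logit_risk = stats::qlogis(pmin(pmax(as.numeric(v), 1e-12),
                                                  1 - 1e-12)))
      if (stats::var(x) == 0)
        stop("degenerate term: ", tm$column, " is constant")
      nm <- if (tm$transform == "identity") tm$column
            else paste0(tm$column, "_", tm$transform)
      cols[[nm]] <- x
    }
  }
  do.call(cbind, cols)
}

# Marginal log-likelihood machinery for a single scalar random intercept.
# Returns a closure over (X, y, g, m) with a warm-started vector of cluster
# modes. At sigma = 0 the marginal likelihood reduces analytically to the
# ordinary logistic likelihood, which the evaluator uses directly.
make_marginal_loglik <- function(X, y, g, m, nodes) {
  # one node is the Laplace approximation: x = 0, weight sqrt(pi)
  gh <- if (nodes == 1L) list(x = 0, w = sqrt(pi))
    else pracma::gaussHermite(nodes)
  K <- length(gh$x)
  node_const <- gh$x^2 + log(gh$w)
  env <- new.env(parent = emptyenv())
  env$u <- rep(0, m)
  function(beta, sigma) {
    eta <- drop(X %*% beta)
    if (sigma < 1e-10) return(bernoulli_loglik(y, eta))
    u <- env$u
    inv_s2 <- 1 / sigma^2
    # Newton iterations for the cluster posterior modes (concave objective)
    for (it in 1:50) {
      s <- eta + u[g]
      mu <- stats::plogis(s)
      grad <- drop(rowsum(y - mu, g)) - u * inv_s2
      hess <- drop(rowsum(mu * (1 - mu), g)) + inv_s2
      step <- grad / hess
      step <- pmin(pmax(step, -5), 5)
      u <- u + step
      if (max(abs(step)) < 1e-9) break
    }
    env$u <- u
    s <- eta + u[g]
    mu <- stats::plogis(s)
    hess <- drop(rowsum(mu * (1 - mu), g)) + inv_s2
    tau <- 1 / sqrt(hess)
    # all nodes at once: Z is m x K, S and the Bernoulli terms n x K
    Z <- u + sqrt(2) * tau %o% gh$x
    S <- eta + Z[g, , drop = FALSE]
    # y*s - log(1 + e^s) written with the stable log-cdf
    CL <- rowsum(y * S + stats::plogis(-S, log.p = TRUE), g)
    L <- CL + stats::dnorm(Z, 0, sigma, log = TRUE) +
      rep(node_const, each = m)
    Mx <- L[cbind(seq_len(m), max.col(L, ties.method = "first"))]
    sum(Mx + log(rowSums(exp(L - Mx))) + log(sqrt(2) * tau))
  }
}

#' Fit a random-intercept logistic regression by adaptive Gauss-Hermite
#' quadrature
#'
#' Maximizes the marginal likelihood of a logistic model with a single
#' normal random intercept per group (hospital), integrating the intercept
#' out by adaptive Gauss-Hermite quadrature centred and scaled at each
#' cluster's posterior mode (one node gives the Laplace approximation).
#' Standard errors come from the observed information (numerical Hessian) of
#' the marginal log-likelihood at the optimum. A variance estimate pinned at
#' the zero boundary is reported with `boundary = TRUE` rather than raised
#' as an error.
#'
#' @param records registry data frame.
#' @param spec a [glmm_spec()].
#' @param sigma optional fixed value for the random-intercept SD; when
#'   supplied only the fixed effects are optimized (useful for likelihood
#'   profiling and for the sigma-zero reduction to ordinary logistic
#'   regression).
#' @param start optional named list with elements `beta` and `sigma`.
#' @return object of class `glmm_fit`: `coefficients`, `se`, `sigma`,
#'   `sigma_se`, `vcov` (fixed effects), `loglik`, `boundary`, `converged`,
#'   `or_table` (odds ratios with 95% Wald intervals), `nodes`, `n`,
#'   `n_groups`.
#' @export
fit_glmm <- function(records, spec, sigma = NULL, start = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  y <- records[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found: ", spec$outcome)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("outcome contains a single class")
  grp <- as.factor(records[[spec$group]])
  if (nlevels(grp) < 2L)
    stop("grouping column ", spec$group, " needs at least 2 levels")
  g <- as.integer(grp)
  m <- nlevels(grp)
  X <- build_glmm_design(records, spec)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):p]], collapse = ", "))

  loglik <- make_marginal_loglik(X, y, g, m, spec$nodes)
  beta0 <- if (!is.null(start$beta)) start$beta
    else fit_logistic(X, y)$coefficients
  sigma0 <- if (!is.null(start$sigma)) start$sigma else 0.2

  # nlminb's convergence code is conservative near the sigma boundary and
  # with finite-difference gradients; an explicit score check at the
  # optimum decides convergence (lower-bound directions may push outward).
  grad_ok <- function(fn, par, lower = NULL, tol = 1e-2) {
    h <- 1e-5 * (1 + abs(par))
    gr <- vapply(seq_along(par), function(j) {
      e <- rep(0, length(par)); e[j] <- h[j]
      (fn(par + e) - fn(par - e)) / (2 * h[j])
    }, numeric(1))
    at_lb <- if (is.null(lower)) rep(FALSE, length(par))
      else par <= lower + 1e-8
    all(abs(gr[!at_lb]) < tol) && all(gr[at_lb] > -tol)
  }

  if (!is.null(sigma)) {
    if (sigma < 0) stop("sigma must be >= 0")
    negll <- function(b) -loglik(b, sigma)
    opt <- stats::nlminb(beta0, negll,
                         control = list(rel.tol = 1e-10, eval.max = 2000,
                                        iter.max = 1000))
    beta <- opt$par
    sig <- sigma
    H <- stats::optimHess(beta, negll)
    vcov_b <- solve(H)
    sigma_se <- NA_real_
    boundary <- sigma == 0
    conv <- opt$convergence == 0 || grad_ok(negll, beta)
    ll <- -opt$objective
  } else {
    negll <- function(par) -loglik(par[seq_len(p)], par[p + 1L])
    lower <- c(rep(-Inf, p), 0)
    opt <- stats::nlminb(c(beta0, sigma0), negll, lower = lower,
                         control = list(rel.tol = 1e-10, eval.max = 3000,
                                        iter.max = 1500))
    par <- opt$par
    beta <- par[seq_len(p)]
    sig <- par[p + 1L]
    boundary <- sig < 1e-4
    conv <- opt$convergence == 0 || grad_ok(negll, par, lower)
    ll <- -opt$objective
    if (boundary) {
      H <- stats::optimHess(beta, function(b) -loglik(b, 0))
      vcov_b <- solve(H)
      sigma_se <- NA_real_
      sig <- 0
    } else {
      H <- stats::optimHess(par, negll)
      V <- tryCatch(solve(H), error = function(e) {
        warning("observed information singular; SEs from fixed-effect block")
        NULL
      })
      if (is.null(V)) {
        vcov_b <- solve(H[seq_len(p), seq_len(p)])
        sigma_se <- NA_real_
      } else {
        vcov_b <- V[seq_len(p), seq_len(p), drop = FALSE]
        sigma_se <- sqrt(max(V[p + 1L, p + 1L], 0))
      }
    }
  }
  if (!conv)
    stop("hierarchical model failed to converge (nlminb message: ",
         opt$message, ")")
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(vcov_b), 0))
  names(se) <- colnames(X)
  z <- stats::qnorm(0.975)
  terms_out <- setdiff(colnames(X), "(Intercept)")
  or_table <- data.frame(
    term = terms_out,
    estimate = beta[terms_out],
    se = se[terms_out],
    or = exp(beta[terms_out]),
    low = exp(beta[terms_out] - z * se[terms_out]),
    high = exp(beta[terms_out] + z * se[terms_out]),
    stringsAsFactors = FALSE)
  rownames(or_table) <- NULL
  structure(list(
    coefficients = beta, se = se, sigma = sig, sigma_se = sigma_se,
    vcov = vcov_b, loglik = ll, boundary = boundary, converged = conv,
    or_table = or_table, nodes = spec$nodes, n = length(y), n_groups = m,
    spec = spec,
    design = list(X = X, y = y, g = g, m = m)
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic fit:", x$n, "patients in", x$n_groups,
      "hospitals;", x$nodes, "quadrature nodes\n")
  cat("sigma =", format(x$sigma, digits = 4),
      if (x$boundary) "(boundary)" else "",
      "; marginal log-likelihood", format(x$loglik, digits = 8), "\n")
  print(x$or_table, digits = 4)
  invisible(x)
}

#' Marginal log-likelihood of a fitted hierarchical model at given
#' parameters
#'
#' Re-evaluates the adaptive-quadrature marginal log-likelihood on the
#' fit's stored design, at arbitrary coefficients, random-intercept SD and
#' node count. At `sigma = 0` this is exactly the ordinary logistic
#' log-likelihood.
#'
#' @param fit a [fit_glmm()] result.
#' @param coefficients fixed-effect vector (defaults to the fit's).
#' @param sigma random-intercept SD (defaults to the fit's).
#' @param nodes quadrature nodes (defaults to the fit's).
#' @return the marginal log-likelihood.
#' @export
glmm_loglik <- function(fit, coefficients = fit$coefficients,
                        sigma = fit$sigma, nodes = fit$nodes) {
  stopifnot(inherits(fit, "glmm_fit"))
  f <- make_marginal_loglik(fit$design$X, fit$design$y, fit$design$g,
                            fit$design$m, nodes)
  f(coefficients, sigma)
}

# Hospital mean annual volume from the registry itself (cases / years),
# optionally counting only laparoscopic cases.
hospital_volume <- function(records, years = 3, ls_only = FALSE) {
  r <- if (ls_only) records[records$ls_flag == 1, , drop = FALSE] else records
  counts <- table(r$hospital_id)
  vol <- as.numeric(counts) / years
  stats::setNames(vol, names(counts))
}

#' Volume-outcome analysis
#'
#' Random-intercept logistic model of operative mortality on hospital
#' procedural volume (entered linearly, odds ratio reported per 10-case
#' annual increase), adjusting for patient clinical risk (logit of the
#' model-expected risk), half-year calendar period and the
#' laparoscopic-versus-open indicator. With `ls_only = TRUE` the analysis is
#' restricted to laparoscopic cases and volume counts laparoscopic cases
#' only. Also returns a display table of O/E mortality by volume category.
#'
#' @param records registry data frame.
#' @param model a mortality [risk_model()].
#' @param years study duration used to annualize volume.
#' @param ls_only restrict to laparoscopic cases.
#' @param include_period adjust for half-year period dummies.
#' @param nodes quadrature nodes.
#' @param volume_breaks right-open cut points for the display table.
#' @return list of class `volume_outcome`: `fit` (a `glmm_fit`; the volume
#'   odds ratio is the `volume_per10` row of its `or_table`) and `display`
#'   (O/E mortality by volume category).
#' @export
volume_outcome_analysis <- function(records, model, years = 3,
                                    ls_only = FALSE, include_period = TRUE,
                                    nodes = 15L,
                                    volume_breaks = c(0, 10, 20, 50, Inf)) {
  r <- if (ls_only) records[records$ls_flag == 1, , drop = FALSE] else records
  if (nrow(r) == 0L) stop("no records in scope")
  vol <- hospital_volume(records, years, ls_only)
  r$volume <- as.numeric(vol[r$hospital_id])
  r$expected_mort <- expected_risk(model, r)
  terms <- list(glmm_term("expected_mort", "logit_risk"))
  if (include_period)
    terms <- c(terms, list(glmm_term("half_year", "dummies",
                                     reference = "1")))
  if (!ls_only && stats::var(r$ls_flag) > 0)
    terms <- c(terms, list(glmm_term("ls_flag", "identity")))
  terms <- c(terms, list(glmm_term("volume", "per10")))
  spec <- glmm_spec("operative_death", terms, nodes = nodes)
  fit <- fit_glmm(r, spec)

  cat_idx <- cut(r$volume, volume_breaks, right = FALSE)
  display <- do.call(rbind, lapply(split(seq_len(nrow(r)), cat_idx),
    function(i) {
      if (!length(i)) return(NULL)
      expc <- sum(r$expected_mort[i])
      data.frame(volume_category = as.character(cat_idx[i[1L]]),
                 n = length(i), observed = sum(r$operative_death[i]),
                 expected = expc,
                 oe = if (expc > 0) sum(r$operative_death[i]) / expc
                      else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(display) <- NULL
  structure(list(fit = fit, display = display, ls_only = ls_only),
            class = "volume_outcome")
}

#' Preference-outcome analysis
#'
#' Random-intercept logistic model of operative mortality on the hospital
#' laparoscopy-preference score, adjusting for patient clinical risk (logit
#' of the model-expected risk), half-year period and hospital procedural
#' volume. In `"categorical"` mode the preference enters as active and low
#' indicators against the standard reference; in `"continuous"` mode as the
#' floored score `max(score, 1)`, so hospitals at or below expected use form
#' the reference. Hospitals whose preference score is undefined (expected
#' laparoscopy count not positive) are excluded with a message.
#'
#' @param records registry data frame.
#' @param summaries a [hospital_preference()] table.
#' @param model a mortality [risk_model()].
#' @param mode `"categorical"` or `"continuous"`.
#' @param include_period adjust for half-year period dummies.
#' @param include_volume adjust for hospital volume (per 10 cases).
#' @param nodes quadrature nodes.
#' @return a `glmm_fit`; in categorical mode the contrasts of interest are
#'   the `categoryactive` and `categorylow` rows of `or_table`, in
#'   continuous mode the `floored` row.
#' @export
preference_outcome_analysis <- function(records, summaries, model,
                                        mode = c("categorical",
                                                 "continuous"),
                                        include_period = TRUE,
                                        include_volume = TRUE,
                                        nodes = 15L) {
  mode <- match.arg(mode)
  ok <- summaries[!is.na(summaries$score), , drop = FALSE]
  dropped <- setdiff(summaries$hospital_id, ok$hospital_id)
  r <- records[records$hospital_id %in% ok$hospital_id, , drop = FALSE]
  if (length(dropped))
    message(length(dropped),
            " hospitals with undefined preference score excluded")
  if (nrow(r) == 0L) stop("no records with a defined preference score")
  idx <- match(r$hospital_id, ok$hospital_id)
  r$category <- ok$category[idx]
  r$floored <- ok$floored[idx]
  r$expected_mort <- expected_risk(model, r)
  # volume is a hospital attribute (total procedural volume), taken from the
  # summary table so that subgroup analyses keep the full-registry volume
  r$volume <- ok$annual_volume[idx]

  terms <- list(glmm_term("expected_mort", "logit_risk"))
  if (include_period)
    terms <- c(terms, list(glmm_term("half_year", "dummies",
                                     reference = "1")))
  if (include_volume && stats::var(r$volume) > 0)
    terms <- c(terms, list(glmm_term("volume", "per10")))
  terms <- c(terms, list(
    if (mode == "categorical")
      glmm_term("category", "dummies", reference = "standard")
    else glmm_term("floored", "identity")))
  fit_glmm(r, glmm_spec("operative_death", terms, nodes = nodes))
}

#' Subgroup analyses of the preference-outcome association
#'
#' Repeats the categorical [preference_outcome_analysis()] within four
#' subgroups: laparoscopic cases only, open cases only, hospitals with
#' annual volume below 20, and hospitals with annual volume of 20 cases per
#' year or more (a volume of exactly 20 falls in the high-volume group).
#' Reports the active-versus-standard odds ratio per subgroup; subgroups in
#' which the model is inestimable (no deaths, missing categories, fit
#' failure) are flagged in the `note` column rather than raised.
#'
#' @inheritParams preference_outcome_analysis
#' @param volume_cut annual-volume split point (default 20 cases/year).
#' @return data frame: subgroup, n, n_deaths, or, low, high, note.
#' @export
subgroup_analyses <- function(records, summaries, model,
                              include_period = TRUE, include_volume = TRUE,
                              nodes = 15L, volume_cut = 20) {
  vol <- stats::setNames(summaries$annual_volume, summaries$hospital_id)
  rec_vol <- as.numeric(vol[records$hospital_id])
  subsets <- list(
    ls = records$ls_flag == 1,
    open = records$ls_flag == 0,
    volume_high = rec_vol >= volume_cut,
    volume_low = rec_vol < volume_cut)
  rows <- lapply(names(subsets), function(nm) {
    r <- records[subsets[[nm]], , drop = FALSE]
    base <- data.frame(subgroup = nm, n = nrow(r),
                       n_deaths = sum(r$operative_death),
                       or = NA_real_, low = NA_real_, high = NA_real_,
                       note = "", stringsAsFactors = FALSE)
    if (nrow(r) == 0L) { base$note <- "empty subgroup"; return(base) }
    if (sum(r$operative_death) == 0L) {
      base$note <- "no deaths; inestimable"; return(base)
    }
    fit <- tryCatch(
      suppressMessages(preference_outcome_analysis(
        r, summaries, model, mode = "categorical",
        include_period = include_period, include_volume = include_volume,
        nodes = nodes)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) { base$note <- fit; return(base) }
    row <- fit$or_table[fit$or_table$term == "categoryactive", , drop = FALSE]
    if (nrow(row) == 0L) {
      base$note <- "active category absent; contrast omitted"
      return(base)
    }
    base$or <- row$or; base$low <- row$low; base$high <- row$high
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
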