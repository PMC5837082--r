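# Clustered binary fixture shared by several blocks
glmm_fixture <- function() cached("glmm_fixture", {
  set.seed(51)
  m <- 80; k <- 50
  g <- rep(1:m, each = k)
  u <- stats::rnorm(m, 0, 0.5)
  x <- stats::rnorm(m * k); z <- stats::rbinom(m * k, 1, 0.4)
  eta <- -2 + 0.6 * x - 0.4 * z + u[g]
  y <- stats::rbinom(m * k, 1, stats::plogis(eta))
  data.frame(hospital_id = sprintf("H%03d", g), y = y, x = x, z = z)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- glmm_fixture()
  spec <- glmm_spec("y", list(glmm_term("x"), glmm_term("z")), nodes = 15)
  fit <- fit_glmm(d, spec)
  ref <- lme4::glmer(y ~ x + z + (1 | hospital_id), data = d,
                     family = stats::binomial(), nAGQ = 15)
  expect_lt(max(abs(fit$coefficients - lme4::fixef(ref))), 1e-3)
  expect_lt(abs(fit$sigma - sqrt(unlist(lme4::VarCorr(ref)))), 1e-2)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(ref))), 1e-3)
  se_ref <- stats::coef(summary(ref))[, "Std. Error"]
  expect_lt(max(abs(fit$se - se_ref)), 1e-3)
})

test_that("sigma-zero data reduce to the ordinary logistic fit", {
  set.seed(33)
  m <- 150; k <- 100
  g <- rep(1:m, each = k)
  x <- stats::rnorm(m * k); b <- stats::rbinom(m * k, 1, 0.3)
  y <- stats::rbinom(m * k, 1, stats::plogis(-2.2 + 0.7 * x - 0.4 * b))
  d <- data.frame(hospital_id = sprintf("H%03d", g), y = y, x = x, b = b)
  fit <- fit_glmm(d, glmm_spec("y", list(glmm_term("x"), glmm_term("b"))))
  ref <- fit_logistic(design_matrix(d, c("x", "b")), y)
  expect_lt(max(abs(fit$coefficients - ref$coefficients)), 1e-4)
  # the marginal likelihood at sigma = 0 is the logistic likelihood
  expect_lt(abs(glmm_loglik(fit, ref$coefficients, sigma = 0) - ref$loglik),
            1e-8)
  # profiling the fixed effects at sigma fixed to 0 gives the same optimum
  fit0 <- fit_glmm(d, glmm_spec("y", list(glmm_term("x"), glmm_term("b"))),
                   sigma = 0)
  expect_true(fit0$boundary)
  expect_lt(max(abs(fit0$coefficients - ref$coefficients)), 1e-4)
})

test_that("quadrature is stable in the node count", {
  d <- glmm_fixture()
  terms <- list(glmm_term("x"), glmm_term("z"))
  f15 <- fit_glmm(d, glmm_spec("y", terms, nodes = 15))
  f25 <- fit_glmm(d, glmm_spec("y", terms, nodes = 25))
  expect_lt(max(abs(f15$coefficients - f25$coefficients)), 1e-3)
  expect_lt(abs(f15$sigma - f25$sigma), 1e-3)
  # Laplace special case runs and lands nearby
  f1 <- fit_glmm(d, glmm_spec("y", terms, nodes = 1))
  expect_lt(max(abs(f1$coefficients - f15$coefficients)), 0.05)
})

test_that("degenerate designs and groupings are rejected", {
  d <- glmm_fixture()
  one <- d[d$hospital_id == "H001", ]
  expect_error(fit_glmm(one, glmm_spec("y", list(glmm_term("x")))),
               "2 levels")
  d2 <- d; d2$const <- 5
  expect_error(fit_glmm(d2, glmm_spec("y", list(glmm_term("const")))),
               "degenerate")
  d3 <- d; d3$y <- 0
  expect_error(fit_glmm(d3, glmm_spec("y", list(glmm_term("x")))),
               "single class")
})

test_that("a planted volume effect is recovered per 10-case increase", {
  # mean over replicates so the Monte-Carlo error of the check itself is
  # well below the 2-SE recovery tolerance
  one <- function(seed) {
    cfg <- sim_config(n_hospitals = 150, volume_median = 40,
                      volume_log_sd = 0.4,
                      mortality_intercept = stats::qlogis(0.03),
                      ls_intercept = stats::qlogis(0.35),
                      sigma_mortality = 0.3,
                      pref_offsets = data.frame(offset = 0, prob = 1,
                                                mort_log_or = 0),
                      seed = seed)
    h <- generate_hospitals(cfg)
    # -0.010 per annual case on the log-odds scale = -0.10 per 10 cases
    h$u_mort <- h$u_mort - 0.010 * (h$annual_volume -
                                      stats::median(h$annual_volume))
    r <- generate_patients(cfg, h)
    m <- fit_risk_model(r, covariate_names())
    vo <- volume_outcome_analysis(r, m, include_period = FALSE)
    row <- vo$fit$or_table[vo$fit$or_table$term == "volume_per10", ]
    if (seed == 701)
      expect_true(all(c("volume_category", "oe") %in% names(vo$display)))
    c(row$estimate, row$se, row$high)
  }
  res <- vapply(701:704, one, numeric(3))
  se_mean <- mean(res[2, ]) / 2
  expect_lt(abs(mean(res[1, ]) - (-0.10)), 2 * se_mean)
  expect_true(all(res[3, ] < 1))  # harmful smallness: CIs exclude the null
})

test_that("null volume effects give near-nominal interval coverage", {
  hits <- 0L; fits <- 0L
  for (s in 1:60) {
    cfg <- sim_config(n_hospitals = 80, volume_median = 10,
                      volume_log_sd = 0.5,
                      mortality_intercept = stats::qlogis(0.05),
                      ls_intercept = stats::qlogis(0.3),
                      sigma_mortality = 0.3,
                      pref_offsets = data.frame(offset = 0, prob = 1,
                                                mort_log_or = 0),
                      seed = 1300 + s)
    r <- simulate_registry(cfg)$records
    m <- fit_risk_model(r, covariate_names())
    vo <- tryCatch(
      volume_outcome_analysis(r, m, include_period = FALSE),
      error = function(e) NULL)
    if (is.null(vo)) next
    fits <- fits + 1L
    row <- vo$fit$or_table[vo$fit$or_table$term == "volume_per10", ]
    if (row$low <= 1 && row$high >= 1) hits <- hits + 1L
  }
  expect_gte(fits, 55L)
  expect_gte(hits / fits, 0.88)
})

test_that("preference harm concentrated in laparoscopic cases shows up in
           the matching subgroup only", {
  cfg <- sim_config(n_hospitals = 140, volume_median = 12,
                    volume_log_sd = 0.3,
                    mortality_intercept = stats::qlogis(0.06),
                    ls_intercept = stats::qlogis(0.3), ls_trend = 0,
                    ls_mort_log_or = 0, sigma_mortality = 0.3,
                    pref_offsets = data.frame(offset = c(-log(9), 0, log(9)),
                                              prob = c(0.35, 0.45, 0.2),
                                              mort_log_or = c(0, 0, 0.9)),
                    pref_mort_scope = "ls", seed = 44)
  r <- simulate_registry(cfg)$records
  m <- fit_risk_model(r, covariate_names())
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf)
  sg <- suppressWarnings(subgroup_analyses(r, hs, m,
                                           include_period = FALSE))
  expect_setequal(sg$subgroup, c("ls", "open", "volume_high", "volume_low"))
  ls_row <- sg[sg$subgroup == "ls", ]
  open_row <- sg[sg$subgroup == "open", ]
  expect_gt(ls_row$low, 1)              # harm visible among LS cases
  expect_true(open_row$low <= 1 && open_row$high >= 1)  # null among open
  # inestimable subgroups carry a note instead of crashing
  expect_true(all(nzchar(sg$note) | !is.na(sg$or)))
})

test_that("preference contrasts degrade gracefully when categories are
           absent", {
  d <- glmm_fixture()
  hs <- data.frame(hospital_id = unique(d$hospital_id))
  hs$procedure <- "DG"
  hs$n_patients <- as.integer(table(d$hospital_id)[hs$hospital_id])
  hs$n_ls <- 0L; hs$expected_ls <- 1
  hs$score <- 1
  hs$category <- factor("standard", c("low", "standard", "active"))
  hs$floored <- 1
  hs$annual_volume <- hs$n_patients / 3
  hs$observed_mortality_pct <- 0; hs$mean_los <- 10; hs$unstable <- FALSE
  d$operative_death <- d$y
  d$half_year <- 1L
  d$procedure <- "DG"
  m <- risk_model("operative_death", intercept = -2,
                  coefficients = c(x = 0.6))
  fit <- NULL
  w <- capture_warnings(
    fit <- preference_outcome_analysis(d, hs, m, "categorical",
                                       include_period = FALSE,
                                       include_volume = FALSE))
  expect_true(any(grepl("omitted", w)))
  expect_false(any(grepl("category", fit$or_table$term)))
})

test_that("a boundary variance estimate is flagged, not raised", {
  set.seed(57)
  m <- 40; k <- 60
  g <- rep(1:m, each = k)
  x <- stats::rnorm(m * k)
  y <- stats::rbinom(m * k, 1, stats::plogis(-1.5 + 0.5 * x))
  d <- data.frame(hospital_id = sprintf("H%02d", g), y = y, x = x)
  fit <- fit_glmm(d, glmm_spec("y", list(glmm_term("x"))))
  if (fit$boundary) {
    expect_identical(fit$sigma, 0)
    expect_true(is.na(fit$sigma_se))
  }
  expect_true(fit$converged)
})
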