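test_that("zero candidates give an intercept-only trace", {
  y <- rep(c(0, 1), 25)
  X <- design_matrix(data.frame(y = y), character())
  tr <- stepwise_logistic(X, y)
  expect_identical(tr$selected, character())
  expect_identical(nrow(tr$steps), 0L)
  expect_equal(unname(tr$fit$coefficients), 0, tolerance = 1e-8)
})

test_that("a strong candidate enters first almost always", {
  first_is_signal <- 0L
  set.seed(21)
  for (i in 1:100) {
    n <- 2000
    d <- data.frame(signal = stats::rnorm(n), n1 = stats::rnorm(n),
                    n2 = stats::rnorm(n), n3 = stats::rnorm(n),
                    n4 = stats::rnorm(n), n5 = stats::rnorm(n))
    y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.0 * d$signal))
    tr <- stepwise_logistic(design_matrix(d, names(d)), y)
    if (nrow(tr$steps) >= 1 && tr$steps$column[1] == "signal")
      first_is_signal <- first_is_signal + 1L
  }
  expect_gte(first_is_signal, 95)
})

test_that("columns that lose significance are removed again", {
  set.seed(22)
  n <- 4000
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  # x1 proxies z1 + z2: marginally strongest, so it enters first, then
  # becomes redundant once both true predictors are in the model
  x1 <- z1 + z2 + stats::rnorm(n, sd = 0.5)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * z1 + 0.8 * z2))
  d <- data.frame(x1 = x1, z1 = z1, z2 = z2)
  tr <- stepwise_logistic(design_matrix(d, c("x1", "z1", "z2")), y)
  expect_setequal(tr$selected, c("z1", "z2"))
  expect_true(any(tr$steps$action == "remove" & tr$steps$column == "x1"))
  # every removed column had previously entered
  rem <- tr$steps$column[tr$steps$action == "remove"]
  ent <- tr$steps$column[tr$steps$action == "enter"]
  expect_true(all(rem %in% ent))
})

test_that("expected laparoscopy count sums predicted probabilities", {
  f <- structure(list(coefficients = c(`(Intercept)` = stats::qlogis(0.3)),
                      converged = TRUE), class = "logistic_fit")
  r <- data.frame(patient_id = 1:10)
  expect_equal(expected_ls_count(f, r), 3, tolerance = 1e-10)

  # intercept-only fit to a whole registry forces n * overall share
  reg <- demo_registry()
  rr <- reg$records
  null_fit <- fit_logistic(design_matrix(rr, character()), rr$ls_flag)
  h1 <- rr[rr$hospital_id == rr$hospital_id[1], ]
  expect_equal(expected_ls_count(null_fit, h1),
               nrow(h1) * mean(rr$ls_flag), tolerance = 1e-8)

  # five printed covariate rows under a 3-coefficient model, hand-summed:
  # eta = -0.5 + 1.2*a - 0.8*b per row
  f3 <- structure(list(
    coefficients = c(`(Intercept)` = -0.5, a = 1.2, b = -0.8),
    converged = TRUE), class = "logistic_fit")
  rows <- data.frame(a = c(0, 1, 1, 0.5, 2), b = c(0, 0, 1, 1, 0.25))
  # expit(-0.5) + expit(0.7) + expit(-0.1) + expit(-0.7) + expit(1.7)
  hand <- 0.37754067 + 0.66818777 + 0.47502081 + 0.33181223 + 0.84553473
  expect_equal(expected_ls_count(f3, rows), hand, tolerance = 1e-7)

  expect_error(expected_ls_count(f3, data.frame(a = 1)), "b")
})

test_that("preference categories follow the half-open thresholds", {
  s <- preference_score(c(0.499, 0.5, 1.999, 2.0), rep(1, 4))
  expect_identical(as.character(s$category),
                   c("low", "standard", "standard", "active"))
  eq <- preference_score(12.5, 12.5)
  expect_equal(eq$score, 1)
  expect_identical(as.character(eq$category), "standard")
  expect_equal(eq$floored, 1)
  act <- preference_score(30, 12.5)
  expect_equal(act$score, 2.4)
  expect_identical(as.character(act$category), "active")
  expect_equal(act$floored, 2.4)
  low <- preference_score(1, 4)
  expect_equal(low$floored, 1)
  expect_error(preference_score(3, 0), "positive")
})

test_that("self-fitted propensity models standardize exactly", {
  reg <- demo_registry()
  r <- reg$records
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf)
  expect_lt(abs(sum(hs$expected_ls) - sum(hs$n_ls)), 1e-6)
  # patient-weighted mean preference score is exactly 1
  expect_equal(sum(hs$expected_ls * hs$score) / sum(hs$expected_ls), 1,
               tolerance = 1e-8)
  # category partition: every scored hospital in exactly one category
  expect_false(any(is.na(hs$category[!is.na(hs$score)])))
  expect_true(all(table(hs$category) ==
                    tapply(hs$score, hs$category, length)[levels(hs$category)],
                  na.rm = TRUE))
})

test_that("estimated preference scores increase with the planted offset", {
  cfg <- sim_config(n_hospitals = 90, volume_median = 25,
                    volume_log_sd = 0.2,
                    ls_intercept = stats::qlogis(0.35), ls_trend = 0,
                    pref_offsets = data.frame(offset = 0, prob = 1,
                                              mort_log_or = 0),
                    seed = 31)
  h <- generate_hospitals(cfg)
  planted <- rep(c(-log(4), 0, log(4)), each = 30)
  h$d_pref <- planted
  r <- generate_patients(cfg, h)
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf)
  mean_by <- tapply(hs$score[match(h$hospital_id, hs$hospital_id)],
                    planted, mean)
  expect_true(all(diff(mean_by) > 0))
})

test_that("group descriptives use the documented quantile convention", {
  hs <- data.frame(
    hospital_id = sprintf("H%02d", 1:5),
    procedure = "DG", n_patients = c(6, 12, 18, 24, 300),
    n_ls = 1, expected_ls = 1, score = 1,
    category = factor("standard", c("low", "standard", "active")),
    floored = 1, annual_volume = c(2, 4, 6, 8, 100),
    observed_mortality_pct = 0, mean_los = 10, unstable = FALSE)
  class(hs) <- c("hospital_summary", class(hs))
  r <- data.frame(hospital_id = rep(hs$hospital_id, times = hs$n_patients),
                  operative_death = 0, length_of_stay = 10)
  g <- preference_group_descriptives(hs, r)
  std <- g[g$category == "standard", ]
  expect_equal(std$volume_median, 6)
  expect_equal(std$volume_q1, 4)
  expect_equal(std$volume_q3, 8)
  expect_identical(attr(g, "quantile_type"), 7L)
  # single-category totals equal whole-registry totals
  expect_equal(std$n_hospitals, 5L)
  expect_equal(std$n_patients, nrow(r))
  # empty categories yield zero-count rows
  expect_equal(g$n_hospitals[g$category == "active"], 0L)
})

test_that("planted small active hospitals reproduce the volume pattern", {
  cfg <- sim_config(n_hospitals = 100, volume_median = 12,
                    volume_log_sd = 0.8,
                    ls_intercept = stats::qlogis(0.3), ls_trend = 0,
                    pref_offsets = data.frame(offset = 0, prob = 1,
                                              mort_log_or = 0),
                    seed = 32)
  h <- generate_hospitals(cfg)
  # plant active preference into the smallest-volume third of hospitals
  ord <- order(h$annual_volume)
  h$d_pref[ord[1:33]] <- log(8)
  h$d_pref[ord[34:100]] <- -0.3
  r <- generate_patients(cfg, h)
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf)
  g <- preference_group_descriptives(hs, r)
  expect_lt(g$volume_median[g$category == "active"],
            g$volume_median[g$category == "standard"])
})

test_that("hospitals with tiny expected counts are flagged unstable", {
  reg <- demo_registry()
  r <- reg$records
  pf <- fit_logistic(design_matrix(r, covariate_names()), r$ls_flag)
  hs <- hospital_preference(r, pf, min_expected = 2)
  expect_true(all(hs$unstable == (hs$expected_ls < 2)))
})
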