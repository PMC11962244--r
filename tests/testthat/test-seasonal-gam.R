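# Seasonal activity-curve models: offset contract, prediction scaling,
# truth recovery on simulated data, and manual likelihood-ratio tests
# cross-checked against an unpenalized GLM oracle.

make_two_effort_data <- function(seed = 1, years = 2003:2008, n = 60) {
  g <- list(generation_pulse(150, 15, 1.2), generation_pulse(230, 15, 3))
  p <- survey_sim_params(years = years, surveys_per_year = n,
                         route_length_km = 2, generations = g, seed = seed)
  simulate_surveys(p)
}

test_that("a constant-rate dataset is fit as a flat unit rate", {
  # counts equal to (integer) effort, i.e. exactly 1 per km
  set.seed(4)
  d <- data.frame(year = rep(2001:2004, each = 60),
                  doy = rep(seq(100, 277, by = 3), 4),
                  count = rep(c(2L, 3L), 120),
                  route_length_km = rep(c(2, 3), 120))
  m <- fit_seasonal_model(d, model_spec("additive", k_doy = 10, k_year = 4))
  pr <- predict_rate_curve(m, 2002, doy = seq(110, 270, 10))
  expect_equal(pr$rate, rep(1, nrow(pr)), tolerance = 1e-3)
  # reference-effort linearity is exact
  pr24 <- predict_rate_curve(m, 2002, doy = seq(110, 270, 10),
                             reference_effort = 2.4)
  expect_equal(pr24$rate, 2.4 * pr$rate, tolerance = 1e-12)
})

test_that("the effort offset contract holds exactly", {
  d <- make_two_effort_data()
  m1 <- fit_seasonal_model(d, model_spec("additive", k_doy = 12, k_year = 4))
  d2 <- d
  d2$route_length_km <- d2$route_length_km * 3
  m2 <- fit_seasonal_model(d2, model_spec("additive", k_doy = 12, k_year = 4))
  # intercept shifts by -log(3); fitted expected counts are unchanged, so
  # the per-km rate curve is divided by exactly 3
  expect_equal(unname(coef(m2)[1] - coef(m1)[1]), -log(3), tolerance = 1e-6)
  expect_equal(fitted(m2), fitted(m1), tolerance = 1e-5)
  g <- seq(120, 320, by = 5)
  expect_equal(3 * predict_rate_curve(m2, 2005, doy = g)$rate,
               predict_rate_curve(m1, 2005, doy = g)$rate, tolerance = 1e-5)
})

test_that("single-pulse simulations are recovered on the rate scale", {
  g <- list(generation_pulse(200, 18, 2.5))
  p <- survey_sim_params(years = 2010:2012, surveys_per_year = 120,
                         route_length_km = 3, generations = g, seed = 8)
  d <- simulate_surveys(p)
  m <- fit_seasonal_model(d, model_spec("doy_only"))
  grid <- seq(min(d$doy), max(d$doy))
  pr <- predict_rate_curve(m, 2011, doy = grid)
  expect_gt(cor(pr$rate, true_rate(p, grid, 2011)), 0.98)
  expect_lte(abs(grid[which.max(pr$rate)] - 200), 3)
})

test_that("count-family validation and extrapolation guards fire", {
  d <- make_two_effort_data()
  d$count[3] <- 1.5
  expect_error(fit_seasonal_model(d, model_spec("doy_only")), "non-integer")
  d <- make_two_effort_data()
  m <- fit_seasonal_model(d, model_spec("doy_only"))
  expect_error(predict_rate_curve(m, 2050), "extrapolate")
  expect_silent(predict_rate_curve(m, 2050, doy = 150:160, extrapolate = TRUE))
  one_year <- d[d$year == 2003, ]
  expect_error(fit_seasonal_model(one_year, model_spec("additive")),
               "2 distinct years")
})

test_that("LRT of a model against itself is null", {
  d <- make_two_effort_data()
  m <- fit_seasonal_model(d, model_spec("additive", k_doy = 8, k_year = 4))
  lt <- lrt_compare(m, m)
  expect_equal(lt$chi2, 0)
  expect_equal(lt$p, 1)
  # non-nested comparison is rejected
  my <- fit_seasonal_model(d, model_spec("year_only", k_year = 4))
  md <- fit_seasonal_model(d, model_spec("doy_only", k_doy = 8))
  expect_error(lrt_compare(my, md), "not nested")
})

test_that("unpenalized fits reproduce a direct GLM and its deviance difference", {
  d <- make_two_effort_data(seed = 3)
  full <- fit_seasonal_model(d, model_spec("additive", k_doy = 6, k_year = 4,
                                           fx = TRUE))
  red <- fit_seasonal_model(d, model_spec("doy_only", k_doy = 6, fx = TRUE))
  # refit both design matrices with plain IRLS as the oracle
  glm_ll <- function(m) {
    X <- stats::model.matrix(m$fit)
    f <- suppressWarnings(
      stats::glm.fit(X, m$data$count, family = stats::poisson(),
                     offset = log(m$data$effort)))
    c(ll = -f$deviance / 2, aic = f$aic)
  }
  ll_full <- glm_ll(full); ll_red <- glm_ll(red)
  chi2_oracle <- 2 * (ll_full[["ll"]] - ll_red[["ll"]])
  lt <- lrt_compare(full, red)
  expect_equal(lt$chi2, chi2_oracle, tolerance = 1e-4)
  expect_equal(lt$edf_diff, full$edf - red$edf, tolerance = 1e-8)
  # unpenalized edf equals the parameter count
  expect_equal(full$edf, length(coef(full)), tolerance = 1e-6)
})

test_that("nested log-likelihoods are monotone", {
  d <- make_two_effort_data(seed = 6)
  specs <- list(model_spec("doy_only", k_doy = 10),
                model_spec("additive", k_doy = 10, k_year = 4),
                model_spec("interaction", k_doy = 10, k_year = 4,
                           engine = "gam"))
  fits <- lapply(specs, fit_seasonal_model, records = d)
  expect_gte(fits[[2]]$loglik, fits[[1]]$loglik - 1e-6)
  expect_gte(fits[[3]]$loglik, fits[[2]]$loglik - 1e-6)
})

test_that("model selection table flags a winner and propagates identity on failure", {
  d <- make_two_effort_data()
  ms1 <- model_selection_table(d, list(model_spec("doy_only", k_doy = 10)))
  expect_equal(nrow(ms1$table), 1)
  expect_null(ms1$tests)
  expect_equal(ms1$winner, "doy_only")
  expect_error(
    model_selection_table(d, list(model_spec("doy_only", k_doy = 200))),
    "doy_only")
})

test_that("a strong year-by-season interaction is selected consistently", {
  g <- list(generation_pulse(150, 12, 2, mean_shift_per_year = 4),
            generation_pulse(230, 12, 5, mean_shift_per_year = -4))
  p <- survey_sim_params(years = 2003:2012, surveys_per_year = 40,
                         route_length_km = 2.5, generations = g)
  specs <- list(model_spec("doy_only", k_doy = 12),
                model_spec("additive", k_doy = 12, k_year = 5),
                model_spec("interaction", k_doy = 12, k_year = 5))
  wins <- vapply(1:50, function(s) {
    p$seed <- 600 + s
    ms <- suppressWarnings(model_selection_table(simulate_surveys(p), specs))
    ms$winner == "interaction"
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("the year-term LRT is calibrated under a no-year-effect null", {
  g <- list(generation_pulse(160, 20, 1.5), generation_pulse(240, 20, 4))
  p <- survey_sim_params(years = 2003:2014, surveys_per_year = 30,
                         route_length_km = 2.5, generations = g)
  rates <- vapply(1:200, function(s) {
    p$seed <- 3000 + s
    d <- simulate_surveys(p)
    # unpenalized bases: integer-df chi-squared reference is exact, so the
    # test must hit its nominal level
    red_fx <- fit_seasonal_model(d, model_spec("doy_only", k_doy = 8,
                                               fx = TRUE))
    full_fx <- fit_seasonal_model(d, model_spec("additive", k_doy = 8,
                                                k_year = 5, fx = TRUE))
    lt_fx <- lrt_compare(full_fx, red_fx)
    # penalized bases: fractional-df reference is approximate and known to
    # be mildly anti-conservative when the penalty is chosen adaptively
    red <- fit_seasonal_model(d, model_spec("doy_only", k_doy = 10))
    fullm <- fit_seasonal_model(d, model_spec("additive", k_doy = 10,
                                              k_year = 5))
    lt <- lrt_compare(fullm, red)
    c(fx = !is.na(lt_fx$p) && lt_fx$p < 0.05,
      pen = !is.na(lt$p) && lt$p < 0.05)
  }, c(fx = TRUE, pen = TRUE))
  expect_lt(abs(mean(rates["fx", ]) - 0.05), 0.03)
  expect_gt(mean(rates["pen", ]), 0.02)
  expect_lt(mean(rates["pen", ]), 0.13)
})
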