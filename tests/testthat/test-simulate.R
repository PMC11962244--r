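# Synthetic-data generators: determinism, structural invariants, and
# agreement of Monte-Carlo means with their closed forms.

test_that("survey generator is deterministic and respects count invariants", {
  p <- survey_sim_params(years = 2005:2008, surveys_per_year = 30, seed = 11)
  d1 <- simulate_surveys(p)
  d2 <- simulate_surveys(p)
  expect_identical(d1, d2)
  expect_true(all(d1$count >= 0))
  expect_true(all(d1$count == round(d1$count)))
  expect_true(all(d1$doy >= day_of_year(as.Date("2005-04-01"))))
  # weekday walks only
  expect_true(all(as.integer(format(d1$date, "%u")) <= 5))
  expect_equal(nrow(d1), 4 * 30)
})

test_that("zero-amplitude pulses give identically zero counts", {
  g <- list(generation_pulse(150, 10, 0), generation_pulse(220, 10, 0))
  p <- survey_sim_params(years = 2010:2012, surveys_per_year = 50,
                         generations = g, seed = 1)
  expect_true(all(simulate_surveys(p)$count == 0))
})

test_that("simulated count means match the closed-form Poisson mean", {
  # one pulse (mean 200, sd 15, amplitude 2/km) on a 2.4 km route:
  # expected count at DOY 200 is 2 * 2.4 = 4.8
  g <- list(generation_pulse(200, 15, 2))
  draws <- numeric(0)
  s <- 0
  while (length(draws) < 1000) {
    s <- s + 1
    p <- survey_sim_params(years = 2003:2052, surveys_per_year = 400,
                           route_length_km = 2.4, generations = g, seed = s)
    d <- simulate_surveys(p)
    draws <- c(draws, d$count[d$doy == 200])
  }
  expect_equal(true_rate(p, 200, 2010), 2)
  se <- sqrt(4.8 / length(draws))
  expect_lt(abs(mean(draws) - 4.8), 3 * se)
})

test_that("expected counts scale linearly with route length", {
  g <- list(generation_pulse(200, 25, 1.5))
  p1 <- survey_sim_params(years = 2003:2032, surveys_per_year = 150,
                          route_length_km = 2, generations = g, seed = 5)
  p2 <- survey_sim_params(years = 2003:2032, surveys_per_year = 150,
                          route_length_km = 4, generations = g, seed = 5)
  m1 <- mean(simulate_surveys(p1)$count)
  m2 <- mean(simulate_surveys(p2)$count)
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("invalid pulse configurations are rejected", {
  bad <- list(generation_pulse(200, 10, 1), generation_pulse(150, 10, 1))
  expect_error(survey_sim_params(generations = bad), "strictly increasing")
  expect_error(generation_pulse(150, 10, -1), "amplitude")
  expect_error(generation_pulse(150, 0, 1), "sd_doy")
  # drift that drives an amplitude negative within the span
  drift <- list(generation_pulse(150, 10, 0.1,
                                 amplitude_trend_per_year = -0.05))
  expect_error(survey_sim_params(years = 2003:2019, generations = drift),
               "non-negative")
})

test_that("specimen generator recovers its quantile trends", {
  # null: all anchor slopes zero -> median trend ~ 0 (median over
  # replicate datasets, each at 500 specimens/yr over 30 years)
  sl0 <- vapply(21:29, function(s) {
    d0 <- simulate_specimens(specimen_sim_params(years = 1989:2018,
                                                 n_per_year = 500, seed = s))
    stopifnot(all(d0$doy >= 1 & d0$doy <= 366))
    fit_quantile_trend(d0, 0.5)$slope
  }, 0)
  expect_lt(abs(median(sl0)), 0.05)
  # injected q90 drift of +0.5 days/yr is recovered at tau = 0.9
  p1 <- specimen_sim_params(years = 1970:2018, n_per_year = 100,
                            slopes = c(q10 = 0, q50 = 0, q90 = 0.5),
                            seed = 22)
  f1 <- fit_quantile_trend(simulate_specimens(p1), 0.9)
  expect_lt(abs(f1$slope - 0.5), 2 * f1$se)
})

test_that("specimen generator handles empty and degenerate requests", {
  p <- specimen_sim_params(n_per_year = 0)
  d <- simulate_specimens(p)
  expect_equal(nrow(d), 0)
  expect_error(specimen_sim_params(anchors = c(q10 = 200, q50 = 185, q90 = 215)),
               "q10 < q50 < q90")
  # a slope that inverts the anchors by the end of the span is rejected
  expect_error(specimen_sim_params(slopes = c(q10 = 2, q50 = 0, q90 = 0)),
               "q10 < q50 < q90")
})

test_that("default specimen pool reproduces the regional design counts", {
  d <- simulate_specimens(specimen_sim_params(seed = 3))
  expect_equal(nrow(d), 463)
  tab <- table(d$region)
  expect_equal(unname(tab[["Iowa"]]), 15)
  expect_equal(unname(tab[["Minnesota"]]), 100)
  expect_equal(unname(tab[["Wisconsin"]]), 348)
})

test_that("experiment generator reproduces the trial design and invariants", {
  d <- simulate_experiment(experiment_sim_params(seed = 9))
  rel <- tapply(d$cages$n_released, d$cages$cohort, sum)
  expect_equal(unname(rel[["earlier"]]), 420)
  expect_equal(unname(rel[["current"]]), 420)
  expect_equal(unname(rel[["later"]]), 280)
  expect_true(all(d$cages$n_eclosed <= d$cages$n_released))
  expect_equal(nrow(d$survivors), sum(d$cages$n_eclosed))
  expect_true(all(d$survivors$dev_days >= 1))
  # determinism
  expect_identical(d, simulate_experiment(experiment_sim_params(seed = 9)))
})

test_that("a cohort with zero survival probability never ecloses", {
  p <- experiment_sim_params(survival = c(earlier = 0, current = 0.2,
                                          later = 0.1), seed = 2)
  d <- simulate_experiment(p)
  expect_true(all(d$cages$n_eclosed[d$cages$cohort == "earlier"] == 0))
})

test_that("cage-level binomial means match the closed form", {
  # no cage heterogeneity: grand survival is exactly binomial with p = 0.095
  ps <- lapply(1:2000, function(s)
    experiment_sim_params(survival = c(a = 0.095, b = 0.5),
                          dev_days = c(a = 20, b = 20),
                          larvae_per_cage = c(a = 30, b = 1),
                          cage_random_sd = 0, seed = 10000 + s))
  rate <- vapply(ps, function(p) {
    d <- simulate_experiment(p)$cages
    sum(d$n_eclosed[d$cohort == "a"]) / sum(d$n_released[d$cohort == "a"])
  }, 0)
  n_draws <- 2000 * 14 * 30
  se <- sqrt(0.095 * 0.905 / n_draws)
  expect_lt(abs(mean(rate) - 0.095), 4 * se)
})
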