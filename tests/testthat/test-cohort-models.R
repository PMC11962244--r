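# Binomial-logit and gaussian mixed models of the caged cohort experiment:
# GLM reductions, Wald tests (cross-checked against car::Anova), interval
# geometry, and recovery/calibration under the generator's truth.

test_that("the zero-variance binomial model reduces to an exact GLM", {
  d <- data.frame(cage = sprintf("C%d", 1:10), site = 1,
                  cohort = rep(c("a", "b"), 5),
                  n_released = 100, n_eclosed = 10)
  f <- fit_survival_glmm(d, random_sd_zero = TRUE)
  expect_equal(unname(f$coef[1]), qlogis(0.1), tolerance = 1e-10)
  expect_equal(f$sd_cage, 0)
  cm <- cohort_means(f)
  expect_equal(cm$estimate, c(0.1, 0.1), tolerance = 1e-10)
})

test_that("the Laplace fit agrees with the GLM when cage variance vanishes", {
  p <- experiment_sim_params(cage_random_sd = 0, seed = 14)
  d <- simulate_experiment(p)
  fg <- fit_survival_glmm(d)
  f0 <- fit_survival_glmm(d, random_sd_zero = TRUE)
  # simulated without cage heterogeneity, the mixed model collapses to the
  # boundary and must reproduce the GLM coefficients
  expect_lt(fg$sd_cage, 1e-4)
  expect_equal(unname(fg$coef), unname(f0$coef), tolerance = 1e-6)
  # optimized likelihood is never below the sd = 0 submodel's
  expect_gte(fg$loglik, f0$loglik - 1e-6)
})

test_that("type II Wald tests match car::Anova on the same fit", {
  d <- simulate_experiment(experiment_sim_params(seed = 5))
  f <- fit_survival_glmm(d)
  w <- type2_wald(f, "cohort")
  ca <- car::Anova(f$fit, type = 2)
  expect_equal(w$chi2, ca[["Chisq"]][1], tolerance = 1e-6)
  expect_equal(w$df, ca[["Df"]][1])
  expect_equal(w$p, ca[["Pr(>Chisq)"]][1], tolerance = 1e-6)
  expect_error(type2_wald(f, "nonexistent"), "not present")
})

test_that("interval geometry follows the reference-distribution closed forms", {
  d <- simulate_experiment(experiment_sim_params(seed = 5))
  f <- fit_survival_glmm(d)
  expect_error(pairwise_intervals(f, level = 0), "level")
  expect_error(pairwise_intervals(f, level = 1), "level")
  hw <- function(ci) qlogis(ci$upper) - qlogis(ci$lower)
  # normal-theory ratio of 83.4% to 95% half-widths on the link scale for
  # the GLM reduction (z reference): qnorm(0.917) / qnorm(0.975) ~ 1.386/1.960
  f0 <- fit_survival_glmm(d, random_sd_zero = TRUE)
  expect_equal(hw(cohort_means(f0, 0.834)) / hw(cohort_means(f0, 0.95)),
               rep(qnorm(0.917) / qnorm(0.975), 3), tolerance = 1e-9)
  # the mixed fit uses a t reference with cage-count df
  expect_equal(f$df_resid, 14 - 3)
  ci83 <- cohort_means(f, level = 0.834)
  ci95 <- cohort_means(f, level = 0.95)
  expect_equal(hw(ci83) / hw(ci95),
               rep(qt(0.917, 11) / qt(0.975, 11), 3), tolerance = 1e-9)
  # endpoints are monotone in the level
  ci60 <- cohort_means(f, level = 0.6)
  expect_true(all(ci60$lower > ci95$lower & ci60$upper < ci95$upper))
  # marginal means shrink toward 1/2 relative to conditional ones
  cm <- cohort_means(f, type = "marginal")
  expect_true(all(abs(qlogis(cm$estimate)) <=
                    abs(qlogis(cohort_means(f)$estimate)) + 1e-8))
})

test_that("complete separation is ridged and flagged", {
  p <- experiment_sim_params(survival = c(earlier = 0, current = 0.2,
                                          later = 0.1), seed = 3)
  d <- simulate_experiment(p)
  expect_warning(f <- fit_survival_glmm(d), "separation")
  expect_true(f$flags$separation_ridge)
  cm <- cohort_means(f)
  expect_true(all(is.finite(qlogis(cm$estimate))))
  expect_lt(cm$estimate[cm$cohort == "earlier"], 0.01)
})

test_that("development-time models recover cell means, dropping empty cohorts", {
  # degenerate zero-variance data: exact cell means, zero uncertainty
  d <- data.frame(cage = rep(c("C1", "C2"), each = 6),
                  cohort = rep(c("current", "later"), each = 6),
                  dev_days = rep(c(22.9, 25), each = 6))
  f <- fit_devtime_lmm(d)
  cm <- cohort_means(f)
  expect_equal(cm$estimate[cm$cohort == "current"], 22.9)
  expect_equal(cm$estimate[cm$cohort == "later"], 25)
  expect_true(isTRUE(f$flags$degenerate))
  # a cohort without survivors is dropped with a warning flag
  p <- experiment_sim_params(survival = c(earlier = 0, current = 0.3,
                                          later = 0.2), seed = 8)
  sim <- simulate_experiment(p)
  expect_warning(f2 <- fit_devtime_lmm(sim), "dropped")
  expect_equal(f2$flags$dropped_cohorts, "earlier")
  expect_equal(nrow(cohort_means(f2)), 2)
})

test_that("development-time estimates recover the generator truth", {
  p <- experiment_sim_params(seed = NULL)
  est <- vapply(1:100, function(s) {
    p$seed <- 7000 + s
    sim <- simulate_experiment(p)
    f <- tryCatch(suppressWarnings(fit_devtime_lmm(sim)),
                  error = function(e) NULL)
    if (is.null(f)) return(c(NA_real_, NA_real_, NA_real_))
    cm <- cohort_means(f)
    vapply(c("earlier", "current", "later"), function(co) {
      v <- cm$estimate[cm$cohort == co]
      if (length(v)) v else NA_real_
    }, 0)
  }, c(earlier = 0, current = 0, later = 0))
  truth <- c(earlier = 33.5, current = 22.9, later = 21.1)
  for (co in names(truth))
    expect_lt(abs(median(est[co, ], na.rm = TRUE) - truth[[co]]), 0.5)
})

test_that("Wald tests are calibrated under equal cohort survival", {
  p <- experiment_sim_params(survival = c(earlier = 0.1, current = 0.1,
                                          later = 0.1),
                             cage_random_sd = 0.4)
  rej <- vapply(1:500, function(s) {
    p$seed <- 20000 + s
    f <- tryCatch(suppressWarnings(
      fit_survival_glmm(simulate_experiment(p))), error = function(e) NULL)
    if (is.null(f)) return(NA)
    type2_wald(f)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.025)
})
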