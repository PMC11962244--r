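# Cohort effects on larval survival and development time from a caged
# release experiment: binomial-logit mixed models with a cage random
# intercept (Laplace approximation, via lme4), gaussian mixed models for
# per-survivor development time (REML), type II Wald tests, and
# back-transformed cohort means with confidence intervals.

#' Confidence level at which non-overlapping error bars correspond to a
#' significant pairwise comparison at alpha = 0.05
#' @export
PAIRWISE_CI_LEVEL <- 0.834

cohort_frame <- function(data) {
  cages <- if (inherits(data, "cohort_data")) data$cages else as.data.frame(data)
  need <- c("cage", "cohort", "n_released", "n_eclosed")
  stop_if(!all(need %in% names(cages)),
          "cage table needs columns ", paste(need, collapse = ", "))
  stop_if(any(cages$n_eclosed > cages$n_released | cages$n_eclosed < 0),
          "need 0 <= n_eclosed <= n_released in every cage")
  lev <- intersect(c("earlier", "current", "later"), unique(cages$cohort))
  if (!length(lev)) lev <- sort(unique(cages$cohort))
  cages$cohort <- factor(cages$cohort, levels = lev)
  cages
}

# weak data-augmentation ridge: one 2-larvae pseudo-cage with 1 success per
# separated cohort, pulling an infinite logit estimate to a finite value
ridge_augment <- function(cages, sep_lev) {
  extra <- do.call(rbind, lapply(sep_lev, function(co)
    data.frame(cage = paste0("ridge_", co), site = NA, cohort = co,
               n_released = 2L, n_eclosed = 1L)))
  extra <- extra[, intersect(names(cages), names(extra)), drop = FALSE]
  for (nm in setdiff(names(cages), names(extra))) extra[[nm]] <- NA
  rbind(cages, extra[names(cages)])
}

new_cohort_fit <- function(model_type, fit, beta, V, sd_cage, loglik,
                           cohorts, flags = list(), df_resid = Inf) {
  # per-cohort link-scale means: intercept plus each treatment dummy
  L <- matrix(0, length(cohorts), length(beta),
              dimnames = list(cohorts, names(beta)))
  L[, 1] <- 1
  for (i in seq_along(cohorts)[-1]) {
    cn <- paste0("cohort", cohorts[i])
    if (cn %in% colnames(L)) L[i, cn] <- 1
  }
  est <- as.numeric(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  structure(list(model_type = model_type, fit = fit, coef = beta, vcov = V,
                 sd_cage = sd_cage, loglik = loglik, cohorts = cohorts,
                 link_means = stats::setNames(est, cohorts),
                 link_se = stats::setNames(se, cohorts),
                 df_resid = df_resid, flags = flags),
            class = "cohort_fit")
}

#' Fit a binomial-logit mixed model of larval survival
#'
#' Survival to eclosion is modelled per cage x cohort release, with the
#' number released as trials and the number eclosing as events, a fixed
#' cohort (release-timing) effect and a cage random intercept integrated
#' out by the Laplace approximation.  Reported cohort survival is the
#' inverse-logit of the cohort fixed effect (conditional on a zero random
#' intercept); see [cohort_means()] for a population-averaged alternative.
#'
#' A cohort with all-zero (or all-success) events across all cages makes
#' the likelihood unbounded (complete separation); the fit then adds a
#' weak data-augmentation ridge (one 2-larvae pseudo-cage with one success
#' per separated cohort) and flags the result.
#'
#' @param data a `cohort_data` object from [simulate_experiment()] /
#'   [read_cohort_csv()], or a cage-level data frame.
#' @param random_sd_zero fix the cage random-intercept SD at 0, reducing
#'   the model to an exact binomial GLM.
#' @return an object of class `cohort_fit`.
#' @export
fit_survival_glmm <- function(data, random_sd_zero = FALSE) {
  cages <- cohort_frame(data)
  stop_if(nlevels(cages$cohort) < 2, "need at least 2 cohorts")
  stop_if(length(unique(cages$cage)) < 2, "need at least 2 cages")
  ev <- tapply(cages$n_eclosed, cages$cohort, sum)
  tr <- tapply(cages$n_released, cages$cohort, sum)
  sep_lev <- names(ev)[ev == 0 | ev == tr]
  flags <- list(separation_ridge = length(sep_lev) > 0)
  if (length(sep_lev)) {
    warning("complete separation in cohort(s) ",
            paste(sep_lev, collapse = ", "),
            "; fitting with a weak data-augmentation ridge", call. = FALSE)
    cages <- ridge_augment(cages, sep_lev)
  }
  if (random_sd_zero) {
    fit <- stats::glm(cbind(n_eclosed, n_released - n_eclosed) ~ cohort,
                      family = stats::binomial(), data = cages)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    sd_cage <- 0
    ll <- as.numeric(stats::logLik(fit))
  } else {
    # bobyqa: the default optimizer intermittently returns a distorted
    # Hessian (absurdly small SEs) on sparse low-survival designs
    fit <- lme4::glmer(cbind(n_eclosed, n_released - n_eclosed) ~ cohort +
                         (1 | cage),
                       family = stats::binomial(), data = cages,
                       control = lme4::glmerControl(optimizer = "bobyqa"))
    conv <- fit@optinfo$conv$lme4
    # optimizer gradient messages are recorded, not fatal: lme4's checks
    # flag many near-boundary fits that are numerically fine
    flags$convergence_warning <- !is.null(conv$code) && conv$code != 0
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sd_cage <- sqrt(unname(lme4::VarCorr(fit)$cage[1]))
    ll <- as.numeric(stats::logLik(fit))
  }
  df_resid <- if (random_sd_zero) Inf
              else length(unique(cages$cage)) - length(beta)
  new_cohort_fit("binomial_glmm", fit, beta, V, sd_cage, ll,
                 levels(cages$cohort), flags, df_resid = df_resid)
}

survivor_frame <- function(data) {
  if (inherits(data, "cohort_data")) return(data$survivors)
  as.data.frame(data)
}

#' Fit a gaussian mixed model of development time
#'
#' Per-survivor development times (days from release to eclosion) are
#' modelled with a fixed cohort effect and a cage random intercept,
#' estimated by REML.  Cohorts with no survivors are dropped with a flag.
#'
#' @param data a `cohort_data` object, or a data frame with columns
#'   `cage`, `cohort`, `dev_days` (one row per survivor).
#' @return an object of class `cohort_fit`.
#' @export
fit_devtime_lmm <- function(data) {
  surv <- survivor_frame(data)
  need <- c("cage", "cohort", "dev_days")
  stop_if(!all(need %in% names(surv)),
          "survivor table needs columns ", paste(need, collapse = ", "))
  # the cohort universe comes from the cage table when available, so that
  # cohorts with zero survivors are reported as dropped rather than unseen
  all_cohorts <- if (inherits(data, "cohort_data"))
    unique(data$cages$cohort) else unique(surv$cohort)
  lev <- intersect(c("earlier", "current", "later"), all_cohorts)
  if (!length(lev)) lev <- sort(unique(all_cohorts))
  present <- lev[lev %in% surv$cohort[!is.na(surv$dev_days)]]
  dropped <- setdiff(lev, present)
  stop_if(length(present) < 2, "need survivors in at least 2 cohorts")
  flags <- list(dropped_cohorts = dropped)
  if (length(dropped))
    warning("cohort(s) with no survivors dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  surv <- surv[surv$cohort %in% present, ]
  surv$cohort <- factor(surv$cohort, levels = present)
  cell_resid <- surv$dev_days -
    stats::ave(surv$dev_days, surv$cohort, surv$cage)
  if (stats::sd(cell_resid) < 1e-10) {
    # degenerate zero-variance data: report exact cell means
    fit <- stats::lm(dev_days ~ cohort, data = surv)
    beta <- stats::coef(fit)
    V <- matrix(0, length(beta), length(beta),
                dimnames = list(names(beta), names(beta)))
    return(new_cohort_fit("gaussian_lmm", fit, beta, V, 0, Inf,
                          present, c(flags, degenerate = TRUE)))
  }
  fit <- lme4::lmer(dev_days ~ cohort + (1 | cage), data = surv, REML = TRUE)
  beta <- lme4::fixef(fit)
  new_cohort_fit("gaussian_lmm", fit, beta,
                 as.matrix(stats::vcov(fit)),
                 sqrt(unname(lme4::VarCorr(fit)$cage[1])),
                 as.numeric(stats::logLik(fit)), present, flags,
                 df_resid = length(unique(surv$cage)) - length(beta))
}

inv_link <- function(fit) {
  if (fit$model_type == "binomial_glmm") stats::plogis else identity
}

#' Back-transformed cohort means with confidence intervals
#'
#' Intervals are computed on the link scale and back-transformed.  Mixed
#' fits use a t reference distribution with cage-count-based degrees of
#' freedom (number of cages minus number of fixed effects), a small-sample
#' correction for the handful of cages the design provides; the
#' fixed-effect-only GLM reduction uses the normal reference.
#'
#' @param fit a `cohort_fit`.
#' @param level confidence level (default 0.95).
#' @param type `"conditional"` (random intercept at 0; the default) or
#'   `"marginal"` (population-averaged over the cage random-intercept
#'   distribution, by Gauss-Hermite quadrature; only differs for the
#'   binomial model).
#' @return data frame with `cohort`, `estimate`, `lower`, `upper`.
#' @export
cohort_means <- function(fit, level = 0.95,
                         type = c("conditional", "marginal")) {
  stopifnot(inherits(fit, "cohort_fit"))
  type <- match.arg(type)
  stop_if(level <= 0 || level >= 1, "level must be in (0, 1)")
  # mixed fits use a t reference with cage-count-based df: with as few as
  # 14 cages, plain normal-theory Wald intervals undercover the truth
  z <- if (is.finite(fit$df_resid)) stats::qt((1 + level) / 2, fit$df_resid)
       else stats::qnorm((1 + level) / 2)
  g <- inv_link(fit)
  est <- fit$link_means
  lo <- est - z * fit$link_se
  hi <- est + z * fit$link_se
  if (type == "marginal" && fit$model_type == "binomial_glmm" &&
      fit$sd_cage > 0) {
    gh <- gauss_hermite(31)
    marg <- function(eta) sum(gh$w * stats::plogis(eta + sqrt(2) * fit$sd_cage * gh$x)) / sqrt(pi)
    out <- data.frame(cohort = fit$cohorts,
                      estimate = vapply(est, marg, 0),
                      lower = vapply(lo, marg, 0),
                      upper = vapply(hi, marg, 0), row.names = NULL)
    attr(out, "level") <- level
    return(out)
  }
  out <- data.frame(cohort = fit$cohorts, estimate = g(est),
                    lower = g(lo), upper = g(hi), row.names = NULL)
  attr(out, "level") <- level
  out
}

# nodes/weights for Gauss-Hermite quadrature (Golub-Welsch)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

#' Type II Wald test of a model term
#'
#' Joint Wald chi-squared test on all coefficients belonging to `term`,
#' using the corresponding block of the fixed-effect covariance matrix.
#' For a single-factor model (the cohort design) this marginal test
#' coincides with `car::Anova(type = 2)`.
#'
#' @param fit a `cohort_fit`.
#' @param term fixed-effect term name (default `"cohort"`).
#' @return list with `chi2`, `df`, `p`.
#' @export
type2_wald <- function(fit, term = "cohort") {
  stopifnot(inherits(fit, "cohort_fit"))
  idx <- which(startsWith(names(fit$coef), term))
  stop_if(!length(idx), "term '", term, "' not present in the fit")
  b <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  kappa_v <- kappa(V)
  if (!all(is.finite(V)) || kappa_v > 1e12)
    stop(sprintf("singular coefficient covariance (condition number %.3g)",
                 kappa_v), call. = FALSE)
  chi2 <- as.numeric(t(b) %*% solve(V, b))
  df <- length(idx)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Cohort intervals for pairwise visual comparison
#'
#' Response-scale intervals at a level (default 83.4%) chosen so that
#' non-overlapping error bars correspond to a significant pairwise
#' difference at alpha = 0.05.
#'
#' @param fit a `cohort_fit`.
#' @param level interval level in (0, 1).
#' @return as [cohort_means()].
#' @export
pairwise_intervals <- function(fit, level = PAIRWISE_CI_LEVEL) {
  cohort_means(fit, level = level)
}

#' @export
print.cohort_fit <- function(x, digits = 3, ...) {
  lbl <- if (x$model_type == "binomial_glmm") "survival" else "development time"
  cat(sprintf("Cohort %s model (%s), cage random-intercept SD = %.3g\n",
              lbl, x$model_type, x$sd_cage))
  w <- type2_wald(x)
  cat(sprintf("  cohort effect: Wald chi2 = %.3g, df = %d, p = %.3g\n",
              w$chi2, w$df, w$p))
  print(cohort_means(x), digits = digits, row.names = FALSE)
  if (isTRUE(x$flags$separation_ridge))
    cat("  [flag] complete separation handled with a weak ridge\n")
  if (length(x$flags$dropped_cohorts))
    cat("  [flag] cohorts dropped (no survivors):",
        paste(x$flags$dropped_cohorts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cohort_fit <- function(object, ...) {
  print(object)
  cat("\n83.4% intervals (non-overlap ~ pairwise significance):\n")
  print(pairwise_intervals(object), row.names = FALSE)
  invisible(object)
}

#' @export
coef.cohort_fit <- function(object, ...) object$coef

#' @export
logLik.cohort_fit <- function(object, ...) object$loglik

#' @export
plot.cohort_fit <- function(x, level = PAIRWISE_CI_LEVEL, ...) {
  cm <- cohort_means(x, level = level)
  n <- nrow(cm)
  ylab <- if (x$model_type == "binomial_glmm")
    "Survival to eclosion" else "Development time (days)"
  graphics::plot(seq_len(n), cm$estimate, xlim = c(0.5, n + 0.5),
                 ylim = range(c(cm$lower, cm$upper)), xaxt = "n",
                 xlab = "Cohort", ylab = ylab, pch = 16, ...)
  graphics::axis(1, at = seq_len(n), labels = cm$cohort)
  graphics::arrows(seq_len(n), cm$lower, seq_len(n), cm$upper,
                   angle = 90, code = 3, length = 0.05)
  invisible(cm)
}
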