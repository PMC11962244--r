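# Penalized-smooth count models of abundance vs day of year and year, with
# a log(effort) offset so counts are standardized per km of route walked.
# mgcv supplies the penalized-likelihood machinery; this module defines the
# model structures, the offset convention, prediction on a reference-effort
# scale, and manual likelihood-ratio comparisons of nested structures.

#' Specify a seasonal count-model structure
#'
#' @param structure one of `"interaction"` (marginal smooths of day of
#'   year and year plus a low-rank tensor-product interaction smooth, so
#'   the additive structure is strictly nested), `"additive"` (separate
#'   smooths of day of year and year), `"doy_only"` or `"year_only"`.
#' @param family `"poisson"` (default; coherent with the log-effort
#'   offset), `"negative_binomial"` or `"gaussian"`.
#' @param k_doy,k_year basis dimensions for the day-of-year and year
#'   marginals (defaults 20 and 8; both must be at least 3).
#' @param fx if `TRUE`, fix the smooths at their full basis dimension with
#'   no penalty (unpenalized regression splines); used mainly to compare
#'   against ordinary GLM fits.
#' @param engine `"gam"`, `"bam"` (fast fitting for the tensor interaction,
#'   used heavily in bootstrap refits) or `"auto"` (bam for the interaction
#'   structure, gam otherwise).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(structure = c("interaction", "additive", "doy_only",
                                     "year_only"),
                       family = c("poisson", "negative_binomial", "gaussian"),
                       k_doy = 20, k_year = 8, fx = FALSE,
                       engine = c("auto", "gam", "bam")) {
  structure <- match.arg(structure)
  family <- match.arg(family)
  engine <- match.arg(engine)
  stop_if(k_doy < 3 || k_year < 3, "basis dimensions must be >= 3")
  structure(list(structure = structure, family = family,
                 k_doy = k_doy, k_year = k_year, fx = fx, engine = engine),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Seasonal model spec: %s, %s family, k_doy = %d, k_year = %d%s\n",
              x$structure, x$family, x$k_doy, x$k_year,
              if (x$fx) " (unpenalized)" else ""))
  invisible(x)
}

spec_formula <- function(spec) {
  fx <- spec$fx
  term <- switch(spec$structure,
    year_only   = sprintf("s(year, k = %d, fx = %s)", spec$k_year, fx),
    doy_only    = sprintf("s(doy, k = %d, fx = %s)", spec$k_doy, fx),
    additive    = sprintf("s(doy, k = %d, fx = %s) + s(year, k = %d, fx = %s)",
                          spec$k_doy, fx, spec$k_year, fx),
    interaction = sprintf(
      "s(doy, k = %d, fx = %s) + s(year, k = %d, fx = %s) + ti(doy, year, k = c(%d, %d), fx = %s)",
      spec$k_doy, fx, spec$k_year, fx,
      min(spec$k_doy, 10L), min(spec$k_year, 5L), fx))
  stats::as.formula(paste("count ~", term, "+ offset(log_effort)"))
}

spec_family <- function(spec) {
  switch(spec$family,
         poisson = stats::poisson(),
         negative_binomial = mgcv::nb(),
         gaussian = stats::gaussian())
}

# normalize input to the columns the fitter needs
as_survey_frame <- function(records) {
  df <- as.data.frame(records)
  eff_col <- intersect(c("route_length_km", "effort"), names(df))
  stop_if(!length(eff_col), "records need a route_length_km (or effort) column")
  names(df)[names(df) == eff_col[1]] <- "effort"
  if (!"doy" %in% names(df)) {
    stop_if(!"date" %in% names(df), "records need doy (or date) and year columns")
    df$doy <- day_of_year(as.Date(df$date))
  }
  if (!"year" %in% names(df) && "date" %in% names(df))
    df$year <- as.integer(format(as.Date(df$date), "%Y"))
  stop_if(!all(c("count", "doy", "year") %in% names(df)),
          "records need count, doy and year columns")
  df
}

#' Fit a seasonal activity-curve model to transect counts
#'
#' Fits a penalized-smooth count model of abundance as a function of day of
#' year and/or year, with `log(route length)` entering as an offset (its
#' coefficient fixed at 1 on the link scale), so the smooth describes the
#' count rate per km.  Smoothing parameters are selected by (f)REML.
#'
#' @param records a `survey_data` frame (or any data frame with columns
#'   `count`, `doy` or `date`, `year`, and `route_length_km`/`effort`).
#' @param spec a [model_spec()].
#' @return an object of class `seasonal_gam`.
#' @export
fit_seasonal_model <- function(records, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  df <- as_survey_frame(records)
  stop_if(any(df$count < 0), "counts must be non-negative")
  stop_if(any(df$effort <= 0), "efforts must be positive")
  stop_if(spec$family != "gaussian" && !is_count(df$count),
          "non-integer counts are not valid under a count family; ",
          "use family = \"gaussian\" or fix the data")
  if (spec$structure != "doy_only")
    stop_if(length(unique(df$year)) < 2,
            "need >= 2 distinct years for a model with a year term")
  if (spec$structure != "year_only")
    stop_if(length(unique(df$doy)) < spec$k_doy,
            "too few distinct days of year for the requested doy basis (k_doy)")
  if (spec$structure %in% c("additive", "year_only", "interaction"))
    stop_if(length(unique(df$year)) < spec$k_year && spec$structure != "interaction",
            "too few distinct years for the requested year basis (k_year)")
  df$log_effort <- log(df$effort)
  engine <- if (spec$engine == "auto") {
    if (spec$structure == "interaction") "bam" else "gam"
  } else spec$engine
  fml <- spec_formula(spec)
  # gam fits use marginal likelihood (ML) so that log-likelihoods of
  # different structures are comparable in manual LRTs; bam (used for fast
  # bootstrap refits of the interaction model) uses its fast-REML method
  fit_gam <- function() mgcv::gam(fml, family = spec_family(spec), data = df,
                                  method = "ML")
  fit <- tryCatch({
    if (engine == "bam") {
      diverged <- FALSE
      f <- withCallingHandlers(
        mgcv::bam(fml, family = spec_family(spec), data = df,
                  method = "fREML", discrete = TRUE),
        warning = function(w) {
          if (grepl("converge", conditionMessage(w))) {
            diverged <<- TRUE
            invokeRestart("muffleWarning")
          }
        })
      # fREML occasionally diverges on very sparse resamples; fall back to
      # the slower but more robust full-REML path
      if (diverged) { engine <- "gam"; f <- fit_gam() }
      f
    } else fit_gam()
  }, error = function(e)
    stop("seasonal model fit failed [", spec$structure, "]: ",
         conditionMessage(e), call. = FALSE))
  # mgcv stores one edf entry per coefficient (parametric entries ~ 1),
  # so the total model edf is the plain sum
  edf_total <- sum(fit$edf)
  structure(list(
    fit = fit, spec = spec, engine = engine,
    loglik = as.numeric(stats::logLik(fit)),
    edf = edf_total,
    aic = stats::AIC(fit),
    data = df,
    doy_range = range(df$doy), years = sort(unique(df$year)),
    efforts = sort(unique(df$effort))
  ), class = "seasonal_gam")
}

#' @export
print.seasonal_gam <- function(x, ...) {
  cat(sprintf("Seasonal activity-curve model (%s, %s family)\n",
              x$spec$structure, x$spec$family))
  cat(sprintf("  %d surveys, years %d-%d, day-of-year %d-%d\n",
              nrow(x$data), min(x$years), max(x$years),
              x$doy_range[1], x$doy_range[2]))
  cat(sprintf("  logLik = %.2f, total edf = %.2f, AIC = %.2f\n",
              x$loglik, x$edf, x$aic))
  invisible(x)
}

#' @export
summary.seasonal_gam <- function(object, ...) summary(object$fit, ...)

#' @export
logLik.seasonal_gam <- function(object, ...) stats::logLik(object$fit)

#' @export
coef.seasonal_gam <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.seasonal_gam <- function(object, ...) stats::fitted(object$fit)

#' Predict the seasonal rate curve for given years
#'
#' Returns the expected count at a stated reference effort (default 1 km,
#' i.e. a per-km rate) on a day-of-year grid.  Because the route length
#' enters the model as an offset with coefficient 1, changing
#' `reference_effort` rescales the curve exactly proportionally.
#'
#' @param object a fitted [fit_seasonal_model()] object.
#' @param years integer vector of years to predict for.
#' @param doy day-of-year grid (default: 1-day grid over the training
#'   range).
#' @param reference_effort effort (km) the curve is standardized to.
#' @param extrapolate allow years outside the training range.
#' @return data frame with columns `year`, `doy`, `rate`.
#' @export
predict_rate_curve <- function(object, years, doy = NULL,
                               reference_effort = 1, extrapolate = FALSE) {
  stopifnot(inherits(object, "seasonal_gam"))
  stop_if(reference_effort <= 0, "reference_effort must be > 0")
  if (is.null(doy)) doy <- seq(object$doy_range[1], object$doy_range[2])
  yr_rng <- range(object$years)
  if (!extrapolate && any(years < yr_rng[1] | years > yr_rng[2]))
    stop("year(s) outside the training range ", yr_rng[1], "-", yr_rng[2],
         "; set extrapolate = TRUE to predict anyway", call. = FALSE)
  nd <- data.frame(doy = rep(doy, length(years)),
                   year = rep(years, each = length(doy)),
                   log_effort = log(reference_effort))
  out <- data.frame(year = nd$year, doy = nd$doy,
                    rate = as.numeric(mgcv::predict.gam(object$fit, nd,
                                                        type = "response")))
  rownames(out) <- NULL
  out
}

#' @export
predict.seasonal_gam <- function(object, years = object$years, ...)
  predict_rate_curve(object, years, ...)

#' @export
plot.seasonal_gam <- function(x, years = x$years, reference_effort = 1, ...) {
  pr <- predict_rate_curve(x, years, reference_effort = reference_effort)
  cols <- grDevices::hcl.colors(length(years), "viridis")
  graphics::plot(NA, xlim = x$doy_range, ylim = c(0, max(pr$rate)),
                 xlab = "Day of year",
                 ylab = sprintf("Expected count (per %g km)", reference_effort),
                 ...)
  for (i in seq_along(years))
    graphics::lines(pr$doy[pr$year == years[i]], pr$rate[pr$year == years[i]],
                    col = cols[i])
  invisible(pr)
}

# strictly-nested structure pairs (reduced -> full)
NESTED_STRUCTURES <- list(
  c("year_only", "additive"), c("doy_only", "additive"),
  c("additive", "interaction"), c("year_only", "interaction"),
  c("doy_only", "interaction"))

is_nested <- function(reduced, full) {
  any(vapply(NESTED_STRUCTURES, function(p)
    p[1] == reduced && p[2] == full, TRUE))
}

#' Likelihood-ratio comparison of nested seasonal models
#'
#' A manual marginal hypothesis test: `chi2 = 2 (logLik_full -
#' logLik_reduced)` referred to a chi-squared distribution whose (possibly
#' fractional) degrees of freedom equal the difference in total effective
#' degrees of freedom between the two penalized fits.
#'
#' @param full,reduced fitted [fit_seasonal_model()] objects on the same
#'   data and family, with `reduced$spec` nested in `full$spec`.
#' @param tol tolerance below which a negative chi-squared is treated as 0.
#' @return list with elements `chi2`, `edf_diff`, `p`, and flags
#'   `caveat_small_df` (edf difference < 0.5) and `convergence_failure`
#'   (chi2 negative beyond tolerance).
#' @export
lrt_compare <- function(full, reduced, tol = 1e-6) {
  stopifnot(inherits(full, "seasonal_gam"), inherits(reduced, "seasonal_gam"))
  same <- identical(full$spec$structure, reduced$spec$structure)
  stop_if(!same && !is_nested(reduced$spec$structure, full$spec$structure),
          "reduced spec (", reduced$spec$structure,
          ") is not nested in full spec (", full$spec$structure, ")")
  stop_if(full$spec$family != reduced$spec$family,
          "models must share a family")
  stop_if(nrow(full$data) != nrow(reduced$data) ||
            !isTRUE(all.equal(sum(full$data$count), sum(reduced$data$count))),
          "models must be fit to the same data")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  convergence_failure <- chi2 < -tol
  chi2 <- max(chi2, 0)
  edf_diff <- full$edf - reduced$edf
  p <- if (chi2 <= tol) 1
       else if (edf_diff > 0) stats::pchisq(chi2, df = edf_diff, lower.tail = FALSE)
       else NA_real_
  structure(list(chi2 = chi2, edf_diff = edf_diff, p = p,
                 caveat_small_df = is.finite(edf_diff) && edf_diff < 0.5,
                 convergence_failure = convergence_failure,
                 full = full$spec$structure, reduced = reduced$spec$structure),
            class = "lrt_compare")
}

#' @export
print.lrt_compare <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi2 = %.2f, edf = %.2f, p = %.3g%s%s\n",
              x$full, x$reduced, x$chi2, x$edf_diff, x$p,
              if (x$caveat_small_df) " [caveat: edf diff < 0.5]" else "",
              if (x$convergence_failure) " [convergence failure]" else ""))
  invisible(x)
}

#' Fit and compare a set of seasonal model structures
#'
#' Fits every spec, tabulates log-likelihood, total edf and AIC, runs
#' likelihood-ratio tests for every nested pair present, and flags a
#' winning model: the lowest-AIC spec among those surviving LRT screening
#' (a fuller structure is screened out when it fails to improve
#' significantly, at `alpha`, on a nested reduced structure that is also in
#' the candidate set).
#'
#' @param records survey data (see [fit_seasonal_model()]).
#' @param specs list of [model_spec()] objects (>= 1).
#' @param alpha screening level for the LRTs.
#' @return an object of class `model_selection` with elements `table`,
#'   `tests`, `winner` (structure name) and `fits`.
#' @export
model_selection_table <- function(records, specs, alpha = 0.05) {
  stop_if(!length(specs), "need at least one spec")
  if (inherits(specs, "model_spec")) specs <- list(specs)
  fits <- lapply(specs, function(sp)
    tryCatch(fit_seasonal_model(records, sp),
             error = function(e) stop("[", sp$structure, "] ",
                                      conditionMessage(e), call. = FALSE)))
  names(fits) <- vapply(specs, function(sp) sp$structure, "")
  tab <- data.frame(
    structure = names(fits),
    family = vapply(fits, function(f) f$spec$family, ""),
    edf = vapply(fits, function(f) f$edf, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    AIC = vapply(fits, function(f) f$aic, 0),
    row.names = NULL)
  tests <- NULL
  if (length(fits) >= 2) {
    for (p in NESTED_STRUCTURES) {
      if (all(p %in% names(fits))) {
        lt <- lrt_compare(fits[[p[2]]], fits[[p[1]]])
        tests <- rbind(tests, data.frame(
          full = p[2], reduced = p[1], chi2 = lt$chi2,
          edf_diff = lt$edf_diff, p = lt$p,
          caveat_small_df = lt$caveat_small_df))
      }
    }
  }
  surviving <- names(fits)
  if (!is.null(tests)) {
    for (i in seq_len(nrow(tests))) {
      if (!is.na(tests$p[i]) && tests$p[i] >= alpha)
        surviving <- setdiff(surviving, tests$full[i])
    }
  }
  if (!length(surviving)) surviving <- names(fits)
  winner <- surviving[which.min(tab$AIC[match(surviving, tab$structure)])]
  tab$winner <- tab$structure == winner
  structure(list(table = tab, tests = tests, winner = winner,
                 fits = fits, alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, digits = 3, ...) {
  cat("Seasonal model comparison\n")
  print(x$table, digits = digits, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nLikelihood-ratio tests\n")
    print(x$tests, digits = digits, row.names = FALSE)
  }
  cat("\nWinning model:", x$winner, "\n")
  invisible(x)
}

#' Serialize a fitted seasonal model to JSON
#'
#' @param object a `seasonal_gam` fit.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "seasonal_gam"))
  x <- list(spec = unclass(object$spec),
            coefficients = as.list(stats::coef(object$fit)),
            smoothing_parameters = as.numeric(object$fit$sp),
            edf_total = object$edf, loglik = object$loglik, aic = object$aic,
            doy_range = object$doy_range, years = object$years,
            efforts = object$efforts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
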