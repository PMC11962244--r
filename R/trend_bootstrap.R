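# Linear year-trends in derived phenometrics, with confidence assessed by
# a resample - refit - rederive bootstrap: survey rows are resampled with
# replacement, the winning seasonal model is refit, per-year curves and
# metrics are rebuilt, and the linear trend is refit, yielding
# sign-specific significance tallies and per-year percentile envelopes.

#' Ordinary least-squares trend of a metric on calendar year
#'
#' @param years numeric vector of years.
#' @param values metric values (may contain `NA`; pairwise-deleted).
#' @param metric metric name carried into the result.
#' @return an object of class `trend_fit`: a list with `metric`, `slope`,
#'   `intercept`, `se`, `t`, `p` and `n_years`.  With fewer than 3
#'   non-missing years all statistics are `NA` (no error).
#' @export
fit_linear_trend <- function(years, values, metric = "metric") {
  ok <- is.finite(years) & is.finite(values)
  n <- sum(ok)
  if (n < 3)
    return(structure(list(metric = metric, slope = NA_real_,
                          intercept = NA_real_, se = NA_real_, t = NA_real_,
                          p = NA_real_, n_years = n), class = "trend_fit"))
  x <- years[ok]; y <- values[ok]
  # closed-form OLS (this runs once per metric per bootstrap replicate)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0)
    return(structure(list(metric = metric, slope = NA_real_,
                          intercept = NA_real_, se = NA_real_, t = NA_real_,
                          p = NA_real_, n_years = n), class = "trend_fit"))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  sigma <- sqrt(rss / (n - 2))
  if (sigma < 1e-10) {
    # degenerate exact fit: a flat metric is "no trend" (p = 1), an exact
    # non-flat line is an infinitely confident trend
    se <- 0
    t <- if (abs(slope) < 1e-12) 0 else Inf * sign(slope)
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    se <- sigma / sqrt(sxx)
    t <- slope / se
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    if (abs(slope) < 1e-12) p <- 1
  }
  structure(list(metric = metric, slope = slope, intercept = intercept,
                 se = se, t = t, p = p, n_years = n), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Linear trend in %s: slope = %.4g /yr (SE %.3g), t = %.3g, p = %.3g, n = %d\n",
              x$metric, x$slope, x$se, x$t, x$p, x$n_years))
  invisible(x)
}

#' Percentile envelope across bootstrap replicates
#'
#' Column-wise empirical percentile band (type-7 interpolation), by default
#' the 16th to 84th percentiles -- analogous to plus/minus one standard
#' error.
#'
#' @param x matrix of replicate values (replicates in rows) or data frame.
#' @param lower,upper percentile bounds in (0, 100), `lower < upper`.
#' @return data frame with one row per column of `x`: `lower`, `upper`,
#'   with the percentile pair in the `"percentiles"` attribute.
#' @export
envelope <- function(x, lower = 16, upper = 84) {
  stop_if(lower >= upper, "lower percentile must be below upper")
  stop_if(lower < 0 || upper > 100, "percentiles must lie in [0, 100]")
  x <- as.matrix(x)
  stop_if(nrow(x) < 2, "need at least 2 replicates")
  lo <- apply(x, 2, stats::quantile, probs = lower / 100, na.rm = TRUE,
              type = 7, names = FALSE)
  hi <- apply(x, 2, stats::quantile, probs = upper / 100, na.rm = TRUE,
              type = 7, names = FALSE)
  out <- data.frame(lower = lo, upper = hi)
  if (!is.null(colnames(x))) rownames(out) <- colnames(x)
  attr(out, "percentiles") <- c(lower, upper)
  out
}

#' Bootstrap confidence assessment of metric trends
#'
#' For each of `n_reps` replicates: resample survey rows with replacement
#' (optionally stratified by year), refit the winning model spec, rebuild
#' each year's curve, rederive the requested phenometrics, and refit the
#' linear year-trend of each metric.  Reports, per metric, the proportion
#' of replicates with a significant (at `alpha`) positive and negative
#' trend, and a per-year percentile envelope of the metric across
#' replicates.
#'
#' Replicates use independent substreams spawned from `seed`, so
#' increasing `n_reps` leaves earlier replicates unchanged.  Replicates
#' whose model fit fails are dropped and counted; more than
#' `max_fail_frac` failures aborts.
#'
#' @param records survey data (see [fit_seasonal_model()]).
#' @param winning_spec the [model_spec()] to refit on every replicate.
#' @param metrics character vector of phenometric column names.
#' @param n_reps number of bootstrap replicates.
#' @param alpha significance level for the sign tallies.
#' @param seed master seed for the replicate substreams.
#' @param stratify_by_year resample within each year (keeps every year
#'   represented in each replicate).
#' @param prominence_frac,reference_effort passed to
#'   [annual_phenometrics()].
#' @param max_fail_frac abort if more than this fraction of replicate fits
#'   fail.
#' @return an object of class `bootstrap_trends`: a list of per-metric
#'   summaries (class `bootstrap_trend`), each with the original trend
#'   fit, replicate slopes and p values, sign tallies and envelope.
#' @export
bootstrap_trends <- function(records, winning_spec,
                             metrics = c("auc_index", "first_peak_doy",
                                         "penult_peak_doy", "last_peak_doy",
                                         "first_peak_height",
                                         "penult_peak_height",
                                         "last_peak_height",
                                         "summer_growth", "total_growth"),
                             n_reps = 500, alpha = 0.05, seed = NULL,
                             stratify_by_year = FALSE,
                             prominence_frac = 0.01, reference_effort = 1,
                             max_fail_frac = 0.2) {
  stop_if(n_reps < 1, "n_reps must be >= 1")
  df <- as_survey_frame(records)
  original <- fit_seasonal_model(df, winning_spec)
  years <- original$years
  met0 <- annual_phenometrics(original, prominence_frac = prominence_frac,
                              reference_effort = reference_effort)
  trend0 <- lapply(metrics, function(m)
    fit_linear_trend(met0$year, met0[[m]], metric = m))
  names(trend0) <- metrics

  seeds <- substream_seeds(seed, n_reps)
  by_year <- split(seq_len(nrow(df)), df$year)
  slope_mat <- matrix(NA_real_, n_reps, length(metrics),
                      dimnames = list(NULL, metrics))
  p_mat <- slope_mat
  metric_arrays <- lapply(metrics, function(m)
    matrix(NA_real_, n_reps, length(years),
           dimnames = list(NULL, years)))
  names(metric_arrays) <- metrics
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    idx <- if (stratify_by_year)
      unlist(lapply(by_year, function(i) sample(i, length(i), replace = TRUE)))
    else sample(nrow(df), nrow(df), replace = TRUE)
    rep_fit <- tryCatch(
      suppressWarnings(fit_seasonal_model(df[idx, , drop = FALSE], winning_spec)),
      error = function(e) NULL)
    if (is.null(rep_fit)) { n_fail <- n_fail + 1L; next }
    mets <- tryCatch(
      annual_phenometrics(rep_fit, years = years,
                          prominence_frac = prominence_frac,
                          reference_effort = reference_effort,
                          doy = seq(original$doy_range[1], original$doy_range[2]),
                          extrapolate = TRUE),
      error = function(e) NULL)
    if (is.null(mets)) { n_fail <- n_fail + 1L; next }
    for (m in metrics) {
      metric_arrays[[m]][r, ] <- mets[[m]]
      tr <- fit_linear_trend(mets$year, mets[[m]], metric = m)
      slope_mat[r, m] <- tr$slope
      p_mat[r, m] <- tr$p
    }
  }
  if (n_fail > max_fail_frac * n_reps)
    stop(sprintf("bootstrap aborted: %d of %d replicate fits failed (> %.0f%%)",
                 n_fail, n_reps, 100 * max_fail_frac), call. = FALSE)

  out <- lapply(metrics, function(m) {
    sl <- slope_mat[, m]; pv <- p_mat[, m]
    ok <- !is.na(sl)
    env <- if (sum(stats::complete.cases(metric_arrays[[m]])) >= 2)
      envelope(metric_arrays[[m]]) else NULL
    structure(list(
      metric = m, n_reps = n_reps, n_fail = n_fail, alpha = alpha,
      original = trend0[[m]], original_values = stats::setNames(met0[[m]], met0$year),
      prop_sig_positive = mean(pv[ok] < alpha & sl[ok] > 0),
      prop_sig_negative = mean(pv[ok] < alpha & sl[ok] < 0),
      slopes = sl, p_values = pv,
      replicate_values = metric_arrays[[m]],
      envelope = env, seed = seed, years = years),
      class = "bootstrap_trend")
  })
  names(out) <- metrics
  structure(out, class = c("bootstrap_trends", "list"))
}

#' @export
print.bootstrap_trend <- function(x, ...) {
  cat(sprintf("Bootstrap trend summary: %s (%d reps, %d failed)\n",
              x$metric, x$n_reps, x$n_fail))
  cat(sprintf("  original slope %.4g /yr (p = %.3g)\n",
              x$original$slope, x$original$p))
  cat(sprintf("  prop. significant (alpha = %.2f): positive %.3f, negative %.3f\n",
              x$alpha, x$prop_sig_positive, x$prop_sig_negative))
  invisible(x)
}

#' @export
print.bootstrap_trends <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}

#' @export
plot.bootstrap_trend <- function(x, ...) {
  yrs <- as.numeric(x$years)
  ylim <- range(c(x$original_values, unlist(x$envelope)), na.rm = TRUE)
  graphics::plot(yrs, x$original_values, type = "n", xlab = "Year",
                 ylab = x$metric, ylim = ylim, ...)
  if (!is.null(x$envelope))
    graphics::polygon(c(yrs, rev(yrs)),
                      c(x$envelope$lower, rev(x$envelope$upper)),
                      col = "grey85", border = NA)
  graphics::lines(yrs, x$original_values, lwd = 2)
  graphics::mtext(sprintf("+%.2f / -%.2f significant",
                          x$prop_sig_positive, x$prop_sig_negative),
                  side = 3, line = 0, adj = 1, cex = 0.8, col = "red3")
  invisible(x)
}
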