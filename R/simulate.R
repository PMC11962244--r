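# Synthetic-data generators.  Each generator draws from exactly the
# statistical structure the downstream analyses assume, and records every
# ground-truth parameter so that recovery and calibration tests can compare
# estimates against known truth.

#' Define a breeding-generation pulse
#'
#' A single within-season generation is modelled as a Gaussian-shaped pulse
#' of expected count rate (per km of route) centred on `mean_doy`.
#' `amplitude` is the expected peak rate per km at the pulse centre.  Both
#' the centre and the amplitude may drift linearly across years, which is
#' how year trends in phenology (peak timing) and within-season growth are
#' injected into simulated surveys.
#'
#' @param mean_doy pulse centre, day of year (1-based) in the first
#'   simulated year.
#' @param sd_doy pulse width (days), must be positive.
#' @param amplitude expected peak count rate per km in the first simulated
#'   year; must be non-negative.
#' @param mean_shift_per_year linear drift of the pulse centre (days/yr).
#' @param amplitude_trend_per_year additive linear drift of the amplitude
#'   (per-km rate units per year).
#' @return an object of class `generation_pulse`.
#' @export
generation_pulse <- function(mean_doy, sd_doy, amplitude,
                             mean_shift_per_year = 0,
                             amplitude_trend_per_year = 0) {
  stop_if(!is.numeric(sd_doy) || sd_doy <= 0, "sd_doy must be > 0")
  stop_if(!is.numeric(amplitude) || amplitude < 0, "amplitude must be >= 0")
  structure(list(mean_doy = mean_doy, sd_doy = sd_doy, amplitude = amplitude,
                 mean_shift_per_year = mean_shift_per_year,
                 amplitude_trend_per_year = amplitude_trend_per_year),
            class = "generation_pulse")
}

#' Default generation pulses for a multivoltine season
#'
#' Four breeding-generation pulses (centres at day-of-year 135, 185, 225
#' and 255 in the first year; width 9 days).  Pulse heights are per-km
#' rates, the scale on which the log-offset model standardizes counts.
#' With `trended = TRUE` the defaults encode the reference study
#' conditions used throughout the package's recovery tests: the last pulse
#' drifts +0.56 days/yr; the first pulse's height doubles across a 17-year
#' span (0.04 to 0.08 per km); the ratio of next-to-last to first pulse
#' height declines from 4.0 to 2.0, and the last-to-first ratio from 17.7
#' to 8.1.  With `trended = FALSE` all pulses are fixed at their
#' first-year values (a null configuration for calibration experiments).
#'
#' @param trended logical; inject the reference year trends?
#' @param span_years number of year steps over which the trended defaults
#'   interpolate their endpoint values (default 16, i.e. a 17-year series).
#' @return list of [generation_pulse()] objects.
#' @export
default_generations <- function(trended = TRUE, span_years = 16) {
  a1_0 <- 0.04                         # first-pulse amp per km, year 0
  a1_1 <- 0.08                         # first-pulse amp per km, final year
  d_a1 <- if (trended) (a1_1 - a1_0) / span_years else 0
  a4_0 <- 17.7 * a1_0                  # total-growth ratio 17.7 at year 0
  a4_1 <- 8.1 * a1_1                   # and 8.1 at the final year
  d_a4 <- if (trended) (a4_1 - a4_0) / span_years else 0
  list(
    generation_pulse(135, 9, a1_0, 0, d_a1),
    generation_pulse(185, 9, 2.4 * a1_0, 0, 0),
    generation_pulse(225, 9, 4.0 * a1_0, 0, 0),
    generation_pulse(255, 9, a4_0, if (trended) 0.56 else 0, d_a4)
  )
}

#' Survey simulation parameters
#'
#' @param years integer vector of consecutive survey years.
#' @param surveys_per_year number of survey walks per year; walks happen on
#'   weekdays between April 1 and November 30 (capped at the number of
#'   available weekdays).
#' @param route_length_km survey effort: either a single value, or a named
#'   numeric vector keyed by year.  The default mirrors a route that was
#'   3.2 km through 2014 and 2.4 km afterwards.
#' @param generations list of [generation_pulse()] objects; centres must be
#'   strictly increasing within every simulated year.
#' @param growth_trend_per_year extra multiplicative year trend applied to
#'   the amplitudes of all pulses after the first (0 = none; the default
#'   pulses already encode a declining growth ratio).
#' @param noise_family `"poisson"` or `"negative_binomial"`.
#' @param nb_size negative-binomial size (overdispersion) parameter.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `survey_sim_params`.
#' @export
survey_sim_params <- function(years = 2003:2019,
                              surveys_per_year = 110,
                              route_length_km = NULL,
                              generations = default_generations(),
                              growth_trend_per_year = 0,
                              noise_family = c("poisson", "negative_binomial"),
                              nb_size = 5,
                              seed = NULL) {
  noise_family <- match.arg(noise_family)
  stop_if(length(years) < 1 || any(diff(years) != 1),
          "years must be a consecutive integer range")
  stop_if(surveys_per_year < 0, "surveys_per_year must be >= 0")
  if (is.null(route_length_km)) {
    route_length_km <- ifelse(years <= 2014, 3.2, 2.4)
    names(route_length_km) <- years
  } else if (length(route_length_km) == 1) {
    route_length_km <- rep(route_length_km, length(years))
    names(route_length_km) <- years
  } else {
    stop_if(is.null(names(route_length_km)) ||
              !all(as.character(years) %in% names(route_length_km)),
            "route_length_km must be scalar or named by year")
    route_length_km <- route_length_km[as.character(years)]
  }
  stop_if(any(route_length_km <= 0), "route lengths must be > 0")
  stop_if(!length(generations) ||
            !all(vapply(generations, inherits, TRUE, "generation_pulse")),
          "generations must be a list of generation_pulse objects")
  # pulse centres must stay strictly increasing and amplitudes non-negative
  # across the simulated span; linear drifts make endpoint checks sufficient
  for (t in c(0, length(years) - 1)) {
    mu <- vapply(generations, function(g) g$mean_doy + g$mean_shift_per_year * t, 0)
    am <- vapply(generations, function(g) g$amplitude + g$amplitude_trend_per_year * t, 0)
    stop_if(any(diff(mu) <= 0),
            "generation means must be strictly increasing within every year")
    stop_if(any(am < 0), "pulse amplitudes must stay non-negative over the year span")
  }
  structure(list(years = years, surveys_per_year = surveys_per_year,
                 route_length_km = route_length_km, generations = generations,
                 growth_trend_per_year = growth_trend_per_year,
                 noise_family = noise_family, nb_size = nb_size, seed = seed),
            class = "survey_sim_params")
}

#' True expected count rate per km under survey simulation parameters
#'
#' Evaluates the noiseless pulse-sum intensity (expected counts per km of
#' route) that [simulate_surveys()] draws from.  Used as the oracle in
#' curve-recovery tests.
#'
#' @param params a [survey_sim_params()] object.
#' @param doy day-of-year vector.
#' @param year a single year inside `params$years`.
#' @return numeric vector of expected counts per km.
#' @export
true_rate <- function(params, doy, year) {
  stopifnot(inherits(params, "survey_sim_params"))
  t <- year - min(params$years)
  rate <- numeric(length(doy))
  for (i in seq_along(params$generations)) {
    g <- params$generations[[i]]
    mu <- g$mean_doy + g$mean_shift_per_year * t
    am <- g$amplitude + g$amplitude_trend_per_year * t
    if (i > 1) am <- am * max(0, 1 + params$growth_trend_per_year * t)
    rate <- rate + am * exp(-0.5 * ((doy - mu) / g$sd_doy)^2)
  }
  rate
}

survey_days <- function(year, surveys_per_year) {
  days <- seq(as.Date(sprintf("%d-04-01", year)),
              as.Date(sprintf("%d-11-30", year)), by = "day")
  days <- days[as.integer(format(days, "%u")) <= 5L]   # weekdays only
  if (surveys_per_year >= length(days)) return(days)
  sort(sample(days, surveys_per_year))
}

#' Simulate transect count surveys
#'
#' Draws one count per simulated weekday walk.  The expected count is
#' `route_length_km * true_rate(doy, year)`; counts come from the Poisson
#' (default) or negative-binomial family.  The returned data frame carries
#' the complete generative truth in its `"truth"` attribute (see
#' [sim_truth()]).
#'
#' @param params a [survey_sim_params()] object.
#' @return a `survey_data` data frame with columns `date`, `year`, `doy`,
#'   `count`, `route_length_km`.
#' @export
simulate_surveys <- function(params) {
  stopifnot(inherits(params, "survey_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  rows <- lapply(params$years, function(y) {
    days <- survey_days(y, params$surveys_per_year)
    doy <- day_of_year(days)
    eff <- unname(params$route_length_km[as.character(y)])
    mu <- eff * true_rate(params, doy, y)
    count <- switch(params$noise_family,
                    poisson = stats::rpois(length(mu), mu),
                    negative_binomial = stats::rnbinom(length(mu), mu = mu,
                                                       size = params$nb_size))
    data.frame(date = days, year = y, doy = doy, count = count,
               route_length_km = eff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- list(params = params, year0 = min(params$years),
                pulse_table = pulse_table(params))
  structure(out, truth = truth, class = c("survey_data", "data.frame"))
}

# per-year table of pulse centres and amplitudes implied by the params
pulse_table <- function(params) {
  do.call(rbind, lapply(params$years, function(y) {
    t <- y - min(params$years)
    do.call(rbind, lapply(seq_along(params$generations), function(i) {
      g <- params$generations[[i]]
      am <- g$amplitude + g$amplitude_trend_per_year * t
      if (i > 1) am <- am * max(0, 1 + params$growth_trend_per_year * t)
      data.frame(year = y, pulse = i,
                 mean_doy = g$mean_doy + g$mean_shift_per_year * t,
                 sd_doy = g$sd_doy, amplitude = am)
    }))
  }))
}

#' Ground truth attached to a simulated dataset
#'
#' @param x an object returned by one of the `simulate_*()` generators.
#' @return the recorded truth list (simulation parameters plus derived
#'   per-year truth values).
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Specimen simulation parameters
#'
#' Collection days of year are drawn from a per-year distribution defined by
#' a piecewise-linear quantile function through three anchors (the 0.1, 0.5
#' and 0.9 quantiles), each drifting linearly across years.  Tails extend
#' the adjacent segment's slope.
#'
#' @param years integer vector of collection years.
#' @param anchors named numeric vector `c(q10=, q50=, q90=)`: anchor days of
#'   year in the first simulated year; must be strictly increasing.
#' @param slopes named numeric vector of per-year drifts for each anchor
#'   (days/yr).
#' @param n_per_year specimens per year; if `NULL`, `n_total` specimens are
#'   spread over years uniformly at random.
#' @param n_total total number of specimens when `n_per_year` is `NULL`.
#'   The default, 463, matches a regional pool of 15 + 100 + 348 records.
#' @param regions named integer vector of per-region record counts used to
#'   label specimens (exact counts when `n_per_year` is `NULL` and
#'   `n_total == sum(regions)`, otherwise sampling weights).
#' @param seed integer seed or `NULL`.
#' @return an object of class `specimen_sim_params`.
#' @export
specimen_sim_params <- function(years = 1970:2018,
                                anchors = c(q10 = 160, q50 = 185, q90 = 215),
                                slopes = c(q10 = 0, q50 = 0, q90 = 0),
                                n_per_year = NULL,
                                n_total = 463,
                                regions = c(Iowa = 15, Minnesota = 100,
                                            Wisconsin = 348),
                                seed = NULL) {
  stopifnot(all(c("q10", "q50", "q90") %in% names(anchors)),
            all(c("q10", "q50", "q90") %in% names(slopes)))
  for (t in c(0, length(years) - 1)) {
    a <- anchors[c("q10", "q50", "q90")] + slopes[c("q10", "q50", "q90")] * t
    stop_if(any(diff(a) <= 0),
            "quantile anchors must satisfy q10 < q50 < q90 in every year")
    stop_if(any(a < 1 | a > 366), "anchor days of year must stay in [1, 366]")
  }
  stop_if(!is.null(n_per_year) && n_per_year < 0, "n_per_year must be >= 0")
  structure(list(years = years, anchors = anchors, slopes = slopes,
                 n_per_year = n_per_year, n_total = n_total,
                 regions = regions, seed = seed),
            class = "specimen_sim_params")
}

#' True quantile function of simulated specimen dates
#'
#' @param params a [specimen_sim_params()] object.
#' @param u probabilities in (0, 1).
#' @param year a single year.
#' @return days of year at the requested quantiles (continuous scale).
#' @export
true_specimen_quantile <- function(params, u, year) {
  stopifnot(inherits(params, "specimen_sim_params"))
  t <- year - min(params$years)
  q <- params$anchors[c("q10", "q50", "q90")] +
    params$slopes[c("q10", "q50", "q90")] * t
  lo_slope <- (q[2] - q[1]) / 0.4
  hi_slope <- (q[3] - q[2]) / 0.4
  out <- ifelse(u <= 0.1, q[1] + (u - 0.1) * lo_slope,
         ifelse(u <= 0.5, q[1] + (u - 0.1) * lo_slope,
         ifelse(u <= 0.9, q[2] + (u - 0.5) * hi_slope,
                q[3] + (u - 0.9) * hi_slope)))
  pmin(pmax(unname(out), 1), 366)
}

#' Simulate specimen collection records
#'
#' @param params a [specimen_sim_params()] object.
#' @return a `specimen_data` data frame with columns `year`, `doy`,
#'   `region`, truth recorded in the `"truth"` attribute.
#' @export
simulate_specimens <- function(params) {
  stopifnot(inherits(params, "specimen_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (!is.null(params$n_per_year)) {
    yrs <- rep(params$years, each = params$n_per_year)
  } else {
    yrs <- sample(params$years, params$n_total, replace = TRUE)
  }
  n <- length(yrs)
  if (n == 0L) {
    out <- data.frame(year = integer(), doy = integer(),
                      region = character())
    return(structure(out, truth = list(params = params),
                     class = c("specimen_data", "data.frame")))
  }
  u <- stats::runif(n)
  doy <- vapply(seq_len(n), function(i)
    true_specimen_quantile(params, u[i], yrs[i]), 0)
  doy <- as.integer(pmin(pmax(round(doy), 1), 366))
  if (is.null(params$n_per_year) && n == sum(params$regions)) {
    region <- sample(rep(names(params$regions), params$regions))
  } else {
    region <- sample(names(params$regions), n, replace = TRUE,
                     prob = params$regions / sum(params$regions))
  }
  out <- data.frame(year = yrs, doy = doy, region = region)
  out <- out[order(out$year, out$doy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, truth = list(params = params),
            class = c("specimen_data", "data.frame"))
}

#' Cohort experiment simulation parameters
#'
#' Emulates a caged larval-release experiment: `n_sites` sites with
#' `cages_per_site` caged host plants each; every cage receives one release
#' per cohort (earlier / current / later timing).  Survival to eclosion is
#' binomial on the logit scale with a shared cage random intercept;
#' development time of each survivor is gaussian, truncated below at 1 day.
#'
#' @param survival named true survival probabilities per cohort (in (0,1)).
#' @param dev_days named true mean development times (days) per cohort.
#' @param n_sites,cages_per_site experiment layout (defaults 2 and 7).
#' @param larvae_per_cage named larvae released per cage for each cohort
#'   (defaults 30, 30, 20).
#' @param cage_random_sd logit-scale SD of the cage random intercept.
#' @param dev_time_sd residual SD of development time (days).
#' @param seed integer seed or `NULL`.
#' @return an object of class `experiment_sim_params`.
#' @export
experiment_sim_params <- function(survival = c(earlier = 0.008,
                                               current = 0.095,
                                               later = 0.048),
                                  dev_days = c(earlier = 33.5,
                                               current = 22.9,
                                               later = 21.1),
                                  n_sites = 2, cages_per_site = 7,
                                  larvae_per_cage = c(earlier = 30,
                                                      current = 30,
                                                      later = 20),
                                  cage_random_sd = 0.5,
                                  dev_time_sd = 2,
                                  seed = NULL) {
  stop_if(any(survival < 0 | survival >= 1),
          "survival probabilities must be in [0, 1)")
  stopifnot(identical(sort(names(survival)), sort(names(dev_days))),
            identical(sort(names(survival)), sort(names(larvae_per_cage))))
  stop_if(cage_random_sd < 0 || dev_time_sd < 0, "SDs must be >= 0")
  structure(list(survival = survival, dev_days = dev_days,
                 n_sites = n_sites, cages_per_site = cages_per_site,
                 larvae_per_cage = larvae_per_cage,
                 cage_random_sd = cage_random_sd, dev_time_sd = dev_time_sd,
                 seed = seed),
            class = "experiment_sim_params")
}

rnorm_trunc1 <- function(n, mean, sd) {
  # gaussian truncated below at 1 day via inverse-cdf sampling
  if (sd == 0) return(pmax(rep(mean, n), 1))
  plo <- stats::pnorm(1, mean, sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, 1))
}

#' Simulate a caged cohort experiment
#'
#' @param params an [experiment_sim_params()] object.
#' @return a `cohort_data` list with elements `cages` (one row per cage x
#'   cohort release: `cage`, `site`, `cohort`, `n_released`, `n_eclosed`)
#'   and `survivors` (one row per surviving individual with its development
#'   time in days).  Truth recorded in the `"truth"` attribute.
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "experiment_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  cohorts <- names(params$survival)
  cage_ids <- as.vector(t(outer(seq_len(params$n_sites),
                                seq_len(params$cages_per_site),
                                function(s, c) sprintf("S%dC%d", s, c))))
  sites <- rep(seq_len(params$n_sites), each = params$cages_per_site)
  u <- stats::rnorm(length(cage_ids), 0, params$cage_random_sd)
  names(u) <- cage_ids
  cages <- do.call(rbind, lapply(cohorts, function(co) {
    n_rel <- params$larvae_per_cage[[co]]
    p <- stats::plogis(stats::qlogis(params$survival[[co]]) + u)
    if (params$survival[[co]] == 0) p <- rep(0, length(u))
    data.frame(cage = cage_ids, site = sites, cohort = co,
               n_released = n_rel,
               n_eclosed = stats::rbinom(length(u), n_rel, p))
  }))
  rownames(cages) <- NULL
  surv_rows <- cages[rep(seq_len(nrow(cages)), cages$n_eclosed),
                     c("cage", "site", "cohort")]
  surv_rows$dev_days <- if (nrow(surv_rows))
    unlist(lapply(seq_len(nrow(cages)), function(i) {
      k <- cages$n_eclosed[i]
      if (k == 0) numeric() else
        rnorm_trunc1(k, params$dev_days[[cages$cohort[i]]], params$dev_time_sd)
    })) else numeric()
  rownames(surv_rows) <- NULL
  structure(list(cages = cages, survivors = surv_rows),
            truth = list(params = params),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Cohort experiment data:", nrow(x$cages), "cage x cohort releases,",
      sum(x$cages$n_released), "larvae released,",
      sum(x$cages$n_eclosed), "eclosed\n")
  tab <- tapply(x$cages$n_eclosed, x$cages$cohort, sum)
  rel <- tapply(x$cages$n_released, x$cages$cohort, sum)
  for (co in names(tab))
    cat(sprintf("  %-8s %d / %d eclosed\n", co, tab[[co]], rel[[co]]))
  invisible(x)
}

#' @export
print.survey_data <- function(x, n = 6, ...) {
  cat("Transect survey data:", nrow(x), "walks,",
      length(unique(x$year)), "years,", sum(x$count), "individuals counted\n")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("# ...", nrow(x) - n, "more rows\n")
  invisible(x)
}
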