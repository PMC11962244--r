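# Phenometrics: statistics derived from a per-year seasonal rate curve --
# peak dates and heights, area under the curve (an abundance index), and
# within-season growth ratios.

#' Find local maxima of a seasonal curve
#'
#' A peak is an interior grid point strictly greater than both neighbours
#' that survives a prominence filter: its prominence (height above the
#' higher of the two bounding saddles, where a saddle is the lowest point
#' between the peak and the nearest higher ground, or the grid edge) must
#' be at least `prominence_frac * max(values)`.  The filter suppresses
#' micro-wiggles of penalized-spline fits; `prominence_frac = 0` disables
#' it.  Boundary points are never returned.
#'
#' @param doy strictly increasing day-of-year grid, spacing at most 1 day,
#'   at least 3 points.
#' @param values curve values on the grid (finite).
#' @param prominence_frac prominence threshold as a fraction of the curve
#'   maximum (default 0.01).
#' @return data frame with columns `doy` and `height`, ordered by `doy`.
#' @export
find_local_maxima <- function(doy, values, prominence_frac = 0.01) {
  stop_if(length(doy) < 3, "grid must have at least 3 points")
  stop_if(length(values) != length(doy), "doy and values lengths differ")
  stop_if(any(diff(doy) <= 0), "grid must be strictly increasing")
  stop_if(max(diff(doy)) > 1 + 1e-8, "grid spacing must be at most 1 day")
  stop_if(!all(is.finite(values)), "curve values must be finite")
  stop_if(prominence_frac < 0, "prominence_frac must be >= 0")
  n <- length(values)
  idx <- which(values[2:(n - 1)] > values[1:(n - 2)] &
                 values[2:(n - 1)] > values[3:n]) + 1L
  if (!length(idx))
    return(data.frame(doy = numeric(), height = numeric()))
  thr <- prominence_frac * max(values)
  keep <- vapply(idx, function(i) peak_prominence(values, i) >= thr, TRUE)
  idx <- idx[keep]
  data.frame(doy = doy[idx], height = values[idx])
}

# height of peak i above the higher of its two bounding saddles
peak_prominence <- function(values, i) {
  n <- length(values)
  left <- values[seq_len(i - 1)]
  higher_l <- which(left > values[i])
  lo_l <- if (length(higher_l)) min(values[(max(higher_l)):(i - 1)]) else min(left)
  right <- values[(i + 1):n]
  higher_r <- which(right > values[i])
  lo_r <- if (length(higher_r)) min(values[(i + 1):(i + min(higher_r))]) else min(right)
  values[i] - max(lo_l, lo_r)
}

#' Area under a seasonal curve
#'
#' Trapezoidal integral of the rate curve over the day-of-year grid; units
#' are expected counts x days at the curve's reference effort.  Used as a
#' relative abundance index.
#'
#' @inheritParams find_local_maxima
#' @return a single non-negative number.
#' @export
curve_auc <- function(doy, values) {
  stop_if(length(doy) < 3, "grid must have at least 3 points")
  stop_if(length(values) != length(doy), "doy and values lengths differ")
  stop_if(any(diff(doy) <= 0), "grid must be strictly increasing")
  stop_if(!all(is.finite(values)), "curve values must be finite")
  sum(diff(doy) * (values[-1] + values[-length(values)]) / 2)
}

#' Derive per-year phenometrics from a seasonal curve
#'
#' Computes, for one year's curve: the dates and heights of the first,
#' next-to-last and last peaks; the area under the curve (abundance
#' index); "summer growth" (next-to-last over first peak height) and
#' "total growth" (last over first peak height).
#'
#' Degenerate peak counts are handled explicitly: with exactly two peaks
#' the next-to-last is taken to be the first (so summer growth is exactly 1
#' and the row is flagged `two_peak_year`); with one peak only the first
#' peak's fields are populated; with none all peak fields are missing while
#' the abundance index is still computed.
#'
#' @inheritParams find_local_maxima
#' @param year year label carried into the output.
#' @return a one-row data frame of class `phenometrics`.
#' @export
derive_metrics <- function(doy, values, year = NA_integer_,
                           prominence_frac = 0.01) {
  pk <- find_local_maxima(doy, values, prominence_frac)
  n <- nrow(pk)
  out <- data.frame(
    year = year,
    first_peak_doy = NA_real_, first_peak_height = NA_real_,
    penult_peak_doy = NA_real_, penult_peak_height = NA_real_,
    last_peak_doy = NA_real_, last_peak_height = NA_real_,
    auc_index = curve_auc(doy, values),
    summer_growth = NA_real_, total_growth = NA_real_,
    n_peaks = n, two_peak_year = FALSE)
  if (n >= 1) {
    out$first_peak_doy <- pk$doy[1]
    out$first_peak_height <- pk$height[1]
  }
  if (n >= 2) {
    out$last_peak_doy <- pk$doy[n]
    out$last_peak_height <- pk$height[n]
    pen <- if (n == 2) 1L else n - 1L
    out$penult_peak_doy <- pk$doy[pen]
    out$penult_peak_height <- pk$height[pen]
    out$two_peak_year <- n == 2
    out$summer_growth <- out$penult_peak_height / out$first_peak_height
    out$total_growth <- out$last_peak_height / out$first_peak_height
  }
  class(out) <- c("phenometrics", "data.frame")
  out
}

#' Per-year phenometrics table from a fitted seasonal model
#'
#' Predicts each year's rate curve on a 1-day grid over the training
#' day-of-year span and derives its phenometrics.
#'
#' @param object a fitted [fit_seasonal_model()] object.
#' @param years years to derive metrics for (default: training years).
#' @param reference_effort effort the curves (hence peak heights and the
#'   abundance index) are standardized to.
#' @param prominence_frac see [find_local_maxima()].
#' @param doy optional day-of-year grid.
#' @param extrapolate allow years outside the model's training range (used
#'   by bootstrap refits, whose resample may miss an extreme year).
#' @return a `phenometrics` data frame, one row per year.
#' @export
annual_phenometrics <- function(object, years = NULL, reference_effort = 1,
                                prominence_frac = 0.01, doy = NULL,
                                extrapolate = FALSE) {
  stopifnot(inherits(object, "seasonal_gam"))
  if (is.null(years)) years <- object$years
  pr <- predict_rate_curve(object, years, doy = doy,
                           reference_effort = reference_effort,
                           extrapolate = extrapolate)
  out <- do.call(rbind, lapply(years, function(y) {
    sub <- pr[pr$year == y, ]
    derive_metrics(sub$doy, sub$rate, year = y,
                   prominence_frac = prominence_frac)
  }))
  rownames(out) <- NULL
  class(out) <- c("phenometrics", "data.frame")
  out
}
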