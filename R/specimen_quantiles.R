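# Quantile-regression trends of specimen collection day-of-year on year.
# The straight-line check-loss minimizer is computed exactly: the loss is
# convex piecewise-linear, the profile over the slope (with the intercept
# concentrated out as a residual quantile) is minimized numerically, and
# the solution is then polished onto the optimal vertex -- a line through
# two data points -- with a deterministic lowest-slope tie-break.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# optimal intercept for fixed slope: tau-quantile of residuals (an order
# statistic is always a minimizer of the one-dimensional check loss)
profile_loss <- function(b, x, y, tau) {
  r <- y - b * x
  a <- stats::quantile(r, tau, type = 1, names = FALSE)
  check_loss(r - a, tau)
}

rq_line_fit <- function(x, y, tau) {
  n <- length(y)
  stop_if(length(unique(x)) < 2, "degenerate design: a single distinct x value")
  # bracket the slope generously around robust and OLS candidates
  b_ols <- stats::cov(x, y) / stats::var(x)
  spread <- (max(y) - min(y)) / (max(x) - min(x))
  half <- 3 * (abs(b_ols) + spread + 1)
  opt <- stats::optimize(profile_loss, c(b_ols - half, b_ols + half),
                         x = x, y = y, tau = tau, tol = 1e-9)
  b0 <- opt$minimum
  r <- y - b0 * x
  a0 <- stats::quantile(r, tau, type = 1, names = FALSE)
  # polish to the optimal vertex: candidate lines through pairs of the
  # points closest to the provisional fit
  ord <- order(abs(r - a0))
  cand_idx <- ord[seq_len(min(length(ord), 10L))]
  best <- c(a0, b0); best_loss <- check_loss(y - a0 - b0 * x, tau)
  for (i in seq_along(cand_idx)) for (j in seq_along(cand_idx)) {
    if (j <= i) next
    i1 <- cand_idx[i]; i2 <- cand_idx[j]
    if (x[i1] == x[i2]) next
    b <- (y[i2] - y[i1]) / (x[i2] - x[i1])
    a <- y[i1] - b * x[i1]
    l <- check_loss(y - a - b * x, tau)
    if (l < best_loss - 1e-12 ||
        (abs(l - best_loss) <= 1e-12 &&
         (b < best[2] - 1e-12 ||
          (abs(b - best[2]) <= 1e-12 && a < best[1] - 1e-12)))) {
      best <- c(a, b); best_loss <- l
    }
  }
  list(coef = c(intercept = best[1], slope = best[2]), loss = best_loss)
}

# Hall-Sheather bandwidth for sparsity estimation at quantile tau
hall_sheather_bw <- function(tau, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  q <- stats::qnorm(tau)
  n^(-1 / 3) * z^(2 / 3) *
    ((1.5 * stats::dnorm(q)^2) / (2 * q^2 + 1))^(1 / 3)
}

# sandwich covariance with local-density (nid-style) weights
rq_vcov_nid <- function(x, y, tau) {
  n <- length(y)
  h <- hall_sheather_bw(tau, n)
  lo <- max(tau - h, 1e-3)
  hi <- min(tau + h, 1 - 1e-3)
  bh <- rq_line_fit(x, y, hi)$coef
  bl <- rq_line_fit(x, y, lo)$coef
  X <- cbind(1, x)
  dy <- as.numeric(X %*% (bh - bl))
  eps <- .Machine$double.eps^(2 / 3)
  f <- pmax(0, (hi - lo) / (dy - eps))
  fxx <- crossprod(X * f, X)
  if (any(!is.finite(fxx)) || rcond(fxx) < 1e-14) {
    # degenerate (e.g. noiseless) data: the local density is unbounded and
    # the sampling variance collapses to zero
    return(matrix(0, 2, 2))
  }
  fxxinv <- solve(fxx)
  tau * (1 - tau) * fxxinv %*% crossprod(X) %*% fxxinv
}

#' Quantile-regression trend of collection day on year
#'
#' Fits the straight line minimizing the asymmetric check loss
#' `sum(rho_tau(doy - a - b * year))`, giving the trend (days/yr) in the
#' `tau`-quantile of the collection-date distribution.  Standard errors use
#' a local-density ("nid"-style) sandwich estimator with the Hall-Sheather
#' bandwidth (or a paired bootstrap); `t = slope / SE` with a two-sided p
#' value on `n - 2` degrees of freedom.
#'
#' @param records data frame with columns `year` and `doy` (a
#'   `specimen_data` frame qualifies); records are pooled across regions.
#' @param tau quantile in (0, 1).
#' @param se `"nid"` (default) or `"boot"`.
#' @param n_boot bootstrap replicates when `se = "boot"`.
#' @param seed seed for the bootstrap SE.
#' @return an object of class `quantile_trend` with `tau`, `coef`
#'   (intercept, slope), `se`, `t`, `p`, `n` and `loss`.
#' @export
fit_quantile_trend <- function(records, tau, se = c("nid", "boot"),
                               n_boot = 200, seed = NULL) {
  se <- match.arg(se)
  stop_if(!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1,
          "tau must be a single number in (0, 1)")
  df <- as.data.frame(records)
  stop_if(!all(c("year", "doy") %in% names(df)),
          "records need year and doy columns")
  df <- df[is.finite(df$year) & is.finite(df$doy), ]
  n <- nrow(df)
  stop_if(n < 10, "need at least 10 records")
  stop_if(length(unique(df$year)) < 3, "need at least 3 distinct years")
  fit <- rq_line_fit(df$year, df$doy, tau)
  slope_se <- if (se == "nid") {
    V <- rq_vcov_nid(df$year, df$doy, tau)
    sqrt(V[2, 2])
  } else {
    if (!is.null(seed)) set.seed(seed)
    sl <- replicate(n_boot, {
      i <- sample(n, n, replace = TRUE)
      tryCatch(rq_line_fit(df$year[i], df$doy[i], tau)$coef[["slope"]],
               error = function(e) NA_real_)
    })
    stats::sd(sl, na.rm = TRUE)
  }
  t <- fit$coef[["slope"]] / slope_se
  structure(list(tau = tau, coef = fit$coef, slope = fit$coef[["slope"]],
                 se = slope_se, t = t,
                 p = 2 * stats::pt(-abs(t), df = n - 2),
                 n = n, loss = fit$loss, se_method = se),
            class = "quantile_trend")
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat(sprintf("Quantile trend (tau = %.2f): slope %.3f +/- %.3f days/yr, t = %.2f, p = %.3g, n = %d\n",
              x$tau, x$slope, x$se, x$t, x$p, x$n))
  invisible(x)
}

#' @export
coef.quantile_trend <- function(object, ...) object$coef

#' @export
predict.quantile_trend <- function(object, year, ...)
  object$coef[["intercept"]] + object$coef[["slope"]] * year

tau_label <- function(tau) {
  if (isTRUE(all.equal(tau, 0.1))) "onset"
  else if (isTRUE(all.equal(tau, 0.5))) "median"
  else if (isTRUE(all.equal(tau, 0.9))) "end"
  else sprintf("tau=%.2g", tau)
}

#' Quantile-phenology trend report
#'
#' Fits one quantile trend per requested `tau` (defaults 0.1, 0.5 and 0.9,
#' representing the onset, median and end of the activity period) and
#' checks whether the fitted quantile lines cross anywhere within the
#' observed year span (a crossing is flagged with a warning, not an
#' error).
#'
#' @inheritParams fit_quantile_trend
#' @param taus quantiles to fit.
#' @return an object of class `quantile_phenology` with a `table` (one row
#'   per tau), the individual `fits`, and a `crossing` flag.
#' @export
quantile_phenology_report <- function(records, taus = c(0.1, 0.5, 0.9),
                                      se = c("nid", "boot")) {
  se <- match.arg(se)
  taus <- sort(taus)
  fits <- lapply(taus, function(tt) fit_quantile_trend(records, tt, se = se))
  tab <- data.frame(
    tau = taus,
    label = vapply(taus, tau_label, ""),
    slope = vapply(fits, function(f) f$slope, 0),
    se = vapply(fits, function(f) f$se, 0),
    t = vapply(fits, function(f) f$t, 0),
    p = vapply(fits, function(f) f$p, 0),
    n = vapply(fits, function(f) f$n, 0L))
  crossing <- FALSE
  if (length(taus) > 1) {
    yr <- range(as.data.frame(records)$year, na.rm = TRUE)
    for (end in yr) {
      v <- vapply(fits, function(f) predict(f, end), 0)
      # non-strict ordering counts: lines that touch within the span are
      # already degenerate as quantile estimates
      if (any(diff(v) <= 1e-8)) crossing <- TRUE
    }
    if (crossing)
      warning("fitted quantile lines cross within the observed year span",
              call. = FALSE)
  }
  structure(list(table = tab, fits = fits, crossing = crossing),
            class = "quantile_phenology")
}

#' @export
print.quantile_phenology <- function(x, digits = 3, ...) {
  cat("Quantile-regression phenology trends (days/yr)\n")
  print(x$table, digits = digits, row.names = FALSE)
  if (x$crossing) cat("NOTE: fitted quantile lines cross within the data span\n")
  invisible(x)
}

#' @export
plot.quantile_phenology <- function(x, records = NULL, ...) {
  if (!is.null(records)) {
    df <- as.data.frame(records)
    graphics::plot(df$year, df$doy, pch = 16, cex = 0.5,
                   col = grDevices::grey(0.4, 0.5),
                   xlab = "Year", ylab = "Collection day of year", ...)
  } else {
    yr <- range(vapply(x$fits, function(f) f$n, 0))
    graphics::plot(NA, xlim = c(1970, 2018), ylim = c(100, 300),
                   xlab = "Year", ylab = "Collection day of year", ...)
  }
  for (f in x$fits) graphics::abline(f$coef[1], f$coef[2], lwd = 2)
  invisible(x)
}
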