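# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

#' Day of year from a Date
#'
#' 1-based day of year (Jan 1 = 1), leap-year aware.
#'
#' @param date a `Date` vector.
#' @return integer vector of days of year.
#' @export
day_of_year <- function(date) {
  stopifnot(inherits(date, "Date"))
  as.POSIXlt(date)$yday + 1L
}

# Deterministic substream seeds: the first n draws from a master-seeded
# stream are unchanged when n grows, so adding replicates never perturbs
# earlier ones.
substream_seeds <- function(master_seed, n) {
  if (!is.null(master_seed)) set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
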