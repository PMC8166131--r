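# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check a scalar is a positive finite number
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

# decimal-year <-> (year, month) helpers used by the climate module;
# month m of year y is represented as y + (m - 0.5)/12
month_to_decimal <- function(year, month) year + (month - 0.5) / 12

# sequence of (year, month) rows spanning two years inclusive
month_grid <- function(from_year, to_year) {
  yrs <- from_year:to_year
  data.frame(year = rep(yrs, each = 12L), month = rep(1:12, length(yrs)))
}
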