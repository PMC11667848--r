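#' Round half away from zero
#'
#' Commercial ("round half up") rounding to an arbitrary granularity, as used
#' for reported prices and patient headcounts. Unlike [base::round()], which
#' rounds half to even, `round_half_up(358.5)` is `359`.
#'
#' @param x Numeric vector.
#' @param granularity Positive rounding step: `1` for headcounts, `1000` for
#'   reported prices per patient per year.
#' @return `x` rounded to the nearest multiple of `granularity`.
#' @examples
#' round_half_up(87399.86, 1000)
#' round_half_up(178.8)
#' @export
round_half_up <- function(x, granularity = 1) {
  stopifnot(is.numeric(x), is.numeric(granularity), granularity > 0)
  floor(x / granularity + 0.5) * granularity
}

#' Round a price for reporting
#'
#' Prices per patient per year are reported rounded to a fixed granularity
#' (default: the nearest thousand euro); full precision is kept internally.
#'
#' @param price_ppppy Unrounded price (EUR per patient per year), vectorised.
#' @param granularity Reporting granularity in EUR (default 1000).
#' @return Rounded price in EUR.
#' @examples
#' report_price(126372.9)
#' @export
report_price <- function(price_ppppy, granularity = 1000) {
  if (any(price_ppppy < 0)) {
    abort("price must be non-negative", class = "omppricer_out_of_range")
  }
  round_half_up(price_ppppy, granularity)
}

# internal condition helpers ------------------------------------------------

stop_missing_key <- function(key) {
  abort(paste0("missing required config key: ", key),
        class = c("omppricer_missing_key", "omppricer_error"))
}

stop_unknown_key <- function(key) {
  abort(paste0("unknown config key: ", key),
        class = c("omppricer_unknown_key", "omppricer_error"))
}

stop_out_of_range <- function(field, value, range) {
  abort(sprintf("field `%s` = %s outside admissible range [%s, %s]",
                field, format(value), format(range[1]), format(range[2])),
        class = c("omppricer_out_of_range", "omppricer_error"))
}

check_range <- function(value, field, lower = -Inf, upper = Inf,
                        lower_open = FALSE, upper_open = FALSE) {
  if (is.null(value) || length(value) != 1 || !is.numeric(value) || is.na(value)) {
    stop_missing_key(field)
  }
  bad <- value < lower || value > upper ||
    (lower_open && value == lower) || (upper_open && value == upper)
  if (bad) stop_out_of_range(field, value, c(lower, upper))
  invisible(value)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
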