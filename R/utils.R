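# Day-count conventions used throughout: "6 months" = 183 days, "3 months" =
# 91 days, "1 year" = 365 days, "2 years" = 730 days, "6 weeks" = 42 days.
# All windows are closed intervals of whole days; dates are Date objects
# (integer days under the hood).

DAYS_6M <- 183L
DAYS_3M <- 91L
DAYS_1Y <- 365L
DAYS_2Y <- 730L
DAYS_6W <- 42L

#' Round half away from zero
#'
#' Base [round()] rounds half to even; published epidemiological tables
#' conventionally round half up. Used for every percentage the package prints.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(0.5)     # 1
#' round_half_up(2.5, 0)  # 3, where round() gives 2
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of n out of total, rounded half-up to `digits` decimals.
pct_of <- function(n, total, digits = 3) {
  round_half_up(100 * n / total, digits)
}

# Calendar year of a Date vector.
year_of <- function(d) as.integer(format(d, "%Y"))

as_day <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

# stopifnot-style contract check with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
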