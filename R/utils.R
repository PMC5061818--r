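#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for pseudo-counts and for the
#' one-decimal percentages in the summary tables. `base::round()` rounds
#' half-to-even, which does not reproduce conventional reported percentages
#' such as 8.2500 -> 8.3.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(8.25004, 1) # 8.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# sign encoding used throughout: integer -1 / 0 / +1
.check_sign <- function(s, what = "sign") {
  if (!all(s %in% c(-1L, 0L, 1L))) {
    stop(sprintf("%s must be -1, 0 or +1", what), call. = FALSE)
  }
  as.integer(s)
}

#' Format integer signs as "+", "0", "-"
#'
#' @param s integer vector in `{-1, 0, 1}`.
#' @return character vector.
#' @export
format_sign <- function(s) {
  s <- .check_sign(s)
  c("-", "0", "+")[s + 2L]
}

#' Parse "+", "0", "-" signs to integers
#'
#' @param s character vector over `{"+", "0", "-"}`.
#' @return integer vector in `{-1, 0, 1}`.
#' @export
parse_sign <- function(s) {
  out <- c("-" = -1L, "0" = 0L, "+" = 1L)[as.character(s)]
  if (anyNA(out)) stop("signs must be one of '+', '0', '-'", call. = FALSE)
  unname(out)
}

.stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
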