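#' @keywords internal
"_PACKAGE"

# Half-up rounding (round-half-even is the R default; cohort reports use the
# convention that 11.35 -> 11.4).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a mutated/total fraction as a percentage
#'
#' Cohort frequency tables report `100 * mutated / total` rounded half-up to
#' one decimal, so 4/35 prints as 11.4 and 1/35 as 2.9.
#'
#' @param mutated Number of mutated samples.
#' @param total Number of samples in the group.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage, rounded half-up.
#' @examples
#' percent_mutated(4, 35)  # 11.4
#' percent_mutated(1, 35)  # 2.9
#' @export
percent_mutated <- function(mutated, total, digits = 1) {
  stopifnot(all(mutated >= 0), all(total > 0), all(mutated <= total))
  round_half_up(100 * mutated / total, digits)
}

stop_missing <- function(df, fields, where) {
  miss <- setdiff(fields, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required field(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
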