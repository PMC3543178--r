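#' Round half away from zero
#'
#' Person counts in the model round half-up at operation boundaries
#' (1107.4 graduates -> 1107, 76.6 separations -> 77, 721.8 -> 722).
#' Base `round()` rounds half to even, which would break the published
#' accounting, so the conventional "round .5 up" rule is applied.
#'
#' @param x numeric vector.
#' @return `x` rounded to whole numbers, halves away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 76.6, 721.8))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# shared validation helpers ------------------------------------------------

check_fraction <- function(x, name, lo = 0, hi = 1, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in [%g, %g]; got %s.",
                  name, lo, hi, paste(format(x[bad]), collapse = ", ")),
          class = "careflow_validation_error")
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` must not be missing.", name),
          class = "careflow_validation_error")
  }
  invisible(x)
}

check_nonneg <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) {
    abort(sprintf("`%s` must be non-negative; got %s.",
                  name, paste(format(x[bad]), collapse = ", ")),
          class = "careflow_validation_error")
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` must not be missing.", name),
          class = "careflow_validation_error")
  }
  invisible(x)
}
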