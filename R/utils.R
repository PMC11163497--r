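#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all reported failure rates. Base [round()] rounds half to even, which
#' would turn 0.45 into 0.4 rather than 0.5 at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.45, 1)   # 0.5
#' round(0.45, 1)           # 0.4 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

stop_segqa <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "segqa_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
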