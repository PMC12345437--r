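#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed tables and for integer bookkeeping at stratum aggregation.
#' Base [round()] rounds half to even, which does not reproduce published
#' percentage tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up (for non-negative input).
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Largest-remainder integer apportionment
#'
#' Distributes an integer `total` across categories proportionally to
#' `weights`, so the parts are integers summing exactly to `total`. Floors
#' the proportional shares and hands the remaining units to the largest
#' fractional remainders (ties broken by first index).
#'
#' @param total Non-negative integer to distribute.
#' @param weights Non-negative numeric weights; must not all be zero unless
#'   `total` is 0.
#' @return Integer vector, same length as `weights`, summing to `total`.
#' @export
apportion <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0) return(rep(0, length(weights)))
  w <- sum(weights)
  if (w == 0) stop("cannot apportion a positive total over all-zero weights")
  exact <- total * weights / w
  base <- floor(exact)
  short <- round(total - sum(base))
  if (short > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  base
}

# shared validation helper: scalar fraction in [0, 1]
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

# draw a sub-seed stream from a master seed without exceeding .Machine$integer.max
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
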