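#' @importFrom stats median pchisq pnorm pt qbeta qnorm rbeta rnorm runif sd
#'   uniroot var
#' @importFrom utils read.csv packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for displayed case counts and
#' monetary amounts.  Base `round()` rounds half to even, which is the wrong
#' convention for reproducing printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# money is carried as integer euro-cents so that sums and products of tariff
# values are exact; conversion rounds half-up at the cent
eur_to_cents <- function(x) round_half_up(x * 100)
cents_to_eur <- function(x) x / 100

abort_input <- function(...) stop(..., call. = FALSE)

# evaluate fn() under set.seed(seed) without disturbing the caller's RNG state
run_seeded <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_input("`seed` must be a single finite integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}
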