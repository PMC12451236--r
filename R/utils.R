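# numerically safe softplus reparameterization used for positivity constraints

softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
}

dsoftplus <- function(x) stats::plogis(x)

logistic <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parameter scale factors mapping raw learnable parameters to physical
# units.  In the package's nA / uS / nF convention every quantity is O(1),
# so the factors are identity; they are kept as a single point of change
# for data recorded on other scales.
I_SCALE <- 1
G_SCALE <- 1
C_SCALE <- 1

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Deterministic child seed
#'
#' Derives a reproducible 31-bit seed from a base seed and a stream label so
#' that independent random streams (initialization, mini-batching, noise)
#' never collide and never overflow R's integer range.
#' @param seed integer base seed.
#' @param stream integer stream index.
#' @return an integer usable with [set.seed()].
#' @keywords internal
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483587L) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
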