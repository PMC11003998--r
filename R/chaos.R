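# Logistic-sine chaotic sequences used to seed populations.  The combined map
# iterates a logistic component a and a sine component b and emits their sum
# modulo one, which spreads initial individuals more evenly over the search
# box than i.i.d. uniform draws.

#' Logistic-sine chaotic sequence
#'
#' Iterates the coupled maps
#' \deqn{a_{i+1} = r a_i (1 - a_i), \quad
#'       b_{i+1} = (4 - r)\sin(\pi b_i)/4, \quad
#'       x_{i+1} = (a_{i+1} + b_{i+1}) \bmod 1}
#' and returns the sequence of \eqn{x} values.
#'
#' @param r Chaos coefficient, in `[0, 4]`; the optimizer default is 0.86.
#' @param a0,b0 Seeds for the two component maps, strictly inside `(0, 1)`.
#' @param length Number of values to produce.
#' @return Numeric vector of `length` values in `[0, 1)`.
#' @export
logistic_sine_sequence <- function(r, a0, b0, length) {
  stopifnot(length >= 1)
  if (!(a0 > 0 && a0 < 1) || !(b0 > 0 && b0 < 1)) {
    stop("a0 and b0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (r < 0 || r > 4) stop("chaos coefficient r must be in [0, 4]", call. = FALSE)
  out <- numeric(length)
  a <- a0; b <- b0
  for (i in seq_len(length)) {
    a <- r * a * (1 - a)
    b <- (4 - r) * sin(pi * b) / 4
    out[i] <- (a + b) %% 1
  }
  out
}

# Stateful chaotic stream: returns a closure producing the next k values, so
# initialization and later dispersal re-draws share one trajectory.
.chaos_stream <- function(r, a0 = NULL, b0 = NULL) {
  eps <- 1e-9
  if (is.null(a0)) a0 <- stats::runif(1, eps, 1 - eps)
  if (is.null(b0)) b0 <- stats::runif(1, eps, 1 - eps)
  a <- a0; b <- b0
  function(k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      a <<- r * a * (1 - a)
      b <<- (4 - r) * sin(pi * b) / 4
      out[i] <- (a + b) %% 1
    }
    out
  }
}

#' Chaotic population initialization
#'
#' Maps a logistic-sine chaotic sequence onto the search box:
#' \eqn{X = lb + x (ub - lb)} per coordinate, filled one individual at a time.
#'
#' @param n Number of individuals (rows).
#' @param lower,upper Bound vectors (length `D`).
#' @param r Chaos coefficient.
#' @param a0,b0 Optional seeds in `(0, 1)`; drawn from the current RNG when
#'   omitted.
#' @return An `n` x `D` matrix of positions inside the box.
#' @export
chaotic_positions <- function(n, lower, upper, r = 0.86, a0 = NULL, b0 = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            all(is.finite(lower)), all(is.finite(upper)))
  d <- length(lower)
  eps <- 1e-9
  if (is.null(a0)) a0 <- stats::runif(1, eps, 1 - eps)
  if (is.null(b0)) b0 <- stats::runif(1, eps, 1 - eps)
  x <- logistic_sine_sequence(r, a0, b0, n * d)
  X <- matrix(x, nrow = n, ncol = d, byrow = TRUE)
  sweep(sweep(X, 2L, upper - lower, "*"), 2L, lower, "+")
}
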