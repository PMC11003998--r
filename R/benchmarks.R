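# CEC2005-style benchmark suite used to validate the continuous optimizer.
# Every function accepts a population matrix (rows = candidate solutions) and
# returns one value per row, so the optimizer can evaluate a whole colony in
# one call.

# Coefficient tables for the fixed-dimension functions.  These are the
# canonical literature tables for the named functions (Kowalik, Hartmann-6,
# Shekel m=10); their known minima (3.0749e-4, -3.3224, -10.5364) match the
# minima quoted for F7, F9, F10.
.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

.hartmann6_a <- matrix(c(
  10,    3,   17,   3.5,  1.7,  8,
  0.05, 10,   17,   0.1,  8,   14,
  3,     3.5,  1.7, 10,  17,    8,
  17,    8,    0.05,10,   0.1, 14), nrow = 4, byrow = TRUE)
.hartmann6_c <- c(1, 1.2, 3, 3.2)
.hartmann6_p <- matrix(c(
  0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
  0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
  0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
  0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381), nrow = 4, byrow = TRUE)

.shekel_a <- matrix(c(
  4, 4, 4, 4,
  1, 1, 1, 1,
  8, 8, 8, 8,
  6, 6, 6, 6,
  3, 7, 3, 7,
  2, 9, 2, 9,
  5, 5, 3, 3,
  8, 1, 8, 1,
  6, 2, 6, 2,
  7, 3.6, 7, 3.6), nrow = 10, byrow = TRUE)
.shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

# Standard penalty term of the generalized penalized functions:
# u(x; a, k, m) = k (x - a)^m above a, 0 on [-a, a], k (-x - a)^m below -a.
.penalty_u <- function(x, a, k, m) {
  out <- x * 0
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  out
}

.benchmark_table <- list(
  F1 = list(dimension = 30L, lower = -100,  upper = 100,  f_min = 0,
            name = "sphere"),
  F2 = list(dimension = 30L, lower = -10,   upper = 10,   f_min = 0,
            name = "Schwefel 2.22 (abs sum + abs product)"),
  F3 = list(dimension = 30L, lower = -100,  upper = 100,  f_min = 0,
            name = "Schwefel 1.2 (rotated hyper-ellipsoid)"),
  F4 = list(dimension = 30L, lower = -5.12, upper = 5.12, f_min = 0,
            name = "Rastrigin"),
  F5 = list(dimension = 30L, lower = -600,  upper = 600,  f_min = 0,
            name = "Griewank"),
  F6 = list(dimension = 30L, lower = -50,   upper = 50,   f_min = 0,
            name = "generalized penalized"),
  F7 = list(dimension = 4L,  lower = -5,    upper = 5,    f_min = 3.075e-4,
            name = "Kowalik"),
  F8 = list(dimension = 2L,  lower = -2,    upper = 2,    f_min = 3,
            name = "Goldstein-Price"),
  F9 = list(dimension = 6L,  lower = 0,     upper = 1,    f_min = -3.32,
            name = "Hartmann-6"),
  F10 = list(dimension = 4L, lower = 0,     upper = 10,   f_min = -10,
             name = "Shekel (m = 10)")
)

#' Benchmark function identifiers
#'
#' @return Character vector `"F1"` ... `"F10"`.
#' @export
benchmark_ids <- function() names(.benchmark_table)

#' Benchmark function specification
#'
#' Dimension, box bounds and known minimum value of one of the ten test
#' functions in the suite.  The suite spans unimodal (F1-F3), multimodal
#' (F4-F6) and fixed-dimension multimodal (F7-F10) functions.
#'
#' @param id One of `benchmark_ids()`.
#' @return A list of class `benchmark_spec` with elements `id`, `name`,
#'   `dimension`, `lower`, `upper` (per-dimension bound vectors) and `f_min`.
#' @export
benchmark_spec <- function(id) {
  id <- as.character(id)[1]
  entry <- .benchmark_table[[id]]
  if (is.null(entry)) {
    stop("unknown benchmark function id: ", id, call. = FALSE)
  }
  structure(list(
    id = id,
    name = entry$name,
    dimension = entry$dimension,
    lower = rep(entry$lower, entry$dimension),
    upper = rep(entry$upper, entry$dimension),
    f_min = entry$f_min
  ), class = "benchmark_spec")
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat(sprintf("%s (%s): D = %d, bounds [%g, %g], f_min = %g\n",
              x$id, x$name, x$dimension, x$lower[1], x$upper[1], x$f_min))
  invisible(x)
}

# Population-matrix evaluators; X is S x D, return length-S vector.
.benchmark_evaluators <- list(
  F1 = function(X, ...) rowSums(X^2),
  F2 = function(X, ...) rowSums(abs(X)) + apply(abs(X), 1L, prod),
  F3 = function(X, ...) {
    C <- t(apply(X, 1L, cumsum))
    if (ncol(X) == 1L) C <- matrix(C, ncol = 1L)
    rowSums(C^2)
  },
  F4 = function(X, ...) rowSums(X^2 - 10 * cos(2 * pi * X) + 10),
  F5 = function(X, ...) {
    d <- ncol(X)
    sq <- sqrt(seq_len(d))
    rowSums(X^2) / 4000 -
      apply(cos(sweep(X, 2L, sq, "/")), 1L, prod) + 1
  },
  F6 = function(X, squared_tail = FALSE, ...) {
    d <- ncol(X)
    xn <- X[, d]
    tail_factor <- 1 + sin(2 * pi * xn)^2
    # As printed the last bracket multiplies an UNSQUARED (x_n - 1); the
    # canonical form of this penalized function squares it.  `squared_tail`
    # selects the canonical variant.
    tail_term <- if (squared_tail) (xn - 1)^2 * tail_factor else
      (xn - 1) * tail_factor
    core <- sin(3 * pi * X[, 1])^2
    if (d > 1L) {
      head <- X[, -d, drop = FALSE]
      nxt <- X[, -1L, drop = FALSE]
      core <- core + rowSums((head - 1)^2 * (1 + sin(3 * pi * nxt)^2))
    }
    0.1 * (core + tail_term) + rowSums(.penalty_u(X, 5, 100, 4))
  },
  F7 = function(X, ...) {
    b <- .kowalik_b
    a <- .kowalik_a
    out <- numeric(nrow(X))
    for (i in seq_along(a)) {
      num <- X[, 1] * (b[i]^2 + b[i] * X[, 2])
      den <- b[i]^2 + b[i] * X[, 3] + X[, 4]
      out <- out + (a[i] - num / den)^2
    }
    out
  },
  F8 = function(X, ...) {
    x1 <- X[, 1]; x2 <- X[, 2]
    term1 <- 1 + (x1 + x2 + 1)^2 *
      (19 - 14 * x1 + 3 * x1^2 - 14 * x2 + 6 * x1 * x2 + 3 * x2^2)
    term2 <- 30 + (2 * x1 - 3 * x2)^2 *
      (18 - 32 * x1 + 12 * x1^2 + 48 * x2 - 36 * x1 * x2 + 27 * x2^2)
    term1 * term2
  },
  F9 = function(X, ...) {
    out <- numeric(nrow(X))
    for (i in 1:4) {
      expo <- numeric(nrow(X))
      for (j in 1:6) {
        expo <- expo + .hartmann6_a[i, j] * (X[, j] - .hartmann6_p[i, j])^2
      }
      out <- out - .hartmann6_c[i] * exp(-expo)
    }
    out
  },
  F10 = function(X, ...) {
    out <- numeric(nrow(X))
    for (i in 1:10) {
      d2 <- rowSums(sweep(X, 2L, .shekel_a[i, ], "-")^2)
      out <- out - 1 / (d2 + .shekel_c[i])
    }
    out
  }
)

#' Evaluate a benchmark function
#'
#' @param id One of `benchmark_ids()`.
#' @param x Numeric vector of length `D`, or an S x D matrix of candidate
#'   solutions (one per row).
#' @param ... Passed to the evaluator; F6 accepts `squared_tail = TRUE` to use
#'   the canonical penalized form whose final `(x_n - 1)` factor is squared
#'   (the default keeps the unsquared factor).
#' @return A single value for a vector `x`, one value per row for a matrix.
#' @export
benchmark_evaluate <- function(id, x, ...) {
  spec <- benchmark_spec(id)
  was_vector <- is.null(dim(x))
  X <- if (was_vector) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) != spec$dimension) {
    stop(sprintf("%s expects dimension %d, got %d", spec$id, spec$dimension,
                 ncol(X)), call. = FALSE)
  }
  out <- .benchmark_evaluators[[spec$id]](X, ...)
  if (was_vector) out[[1L]] else out
}
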