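## Not-a-knot cubic spline interpolation with closed-form integration.
##
## The derivative profiles are interpolated with a cubic spline and the
## integral taken analytically, piecewise. Not-a-knot end conditions
## (third derivative continuous across the second and next-to-last knots)
## are used; stats::splinefun offers "fmm" and "natural" but not this one,
## so the tridiagonal moment system is solved here directly.

## Second derivatives (moments) of the not-a-knot spline at the knots.
.nak_moments <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i]     <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  # S''' continuous at x[2] and x[n-1]
  A[1, 1] <- 1 / h[1]; A[1, 2] <- -(1 / h[1] + 1 / h[2]); A[1, 3] <- 1 / h[2]
  A[n, n - 2] <- 1 / h[n - 2]
  A[n, n - 1] <- -(1 / h[n - 2] + 1 / h[n - 1])
  A[n, n] <- 1 / h[n - 1]
  solve(A, b)
}

## Exact integral of the spline over the full knot range.
.nak_integral <- function(x, y) {
  n <- length(x)
  M <- .nak_moments(x, y)
  h <- diff(x)
  sum(h * (y[-n] + y[-1]) / 2 - h^3 * (M[-n] + M[-1]) / 24)
}

## Quadrature weights w such that integral = sum(w * y) (the integral is
## linear in the ordinates). Used for error propagation.
.nak_weights <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    .nak_integral(x, e)
  }, numeric(1))
}

#' Not-a-knot cubic spline interpolant
#'
#' Builds the not-a-knot cubic spline through `(x, y)` and returns the
#' interpolant together with its exact piecewise-polynomial integral.
#'
#' @param x Strictly increasing knots (at least 3).
#' @param y Ordinates.
#' @return A list with `predict(xx)`, the interpolant, and
#'   `integral(a, b)`, the analytic integral of the spline (defaults to the
#'   full knot range).
#' @examples
#' sp <- notaknot_spline(seq(0, 1, 0.25), 12 * seq(0, 1, 0.25)^2)
#' sp$integral()  # exactly 4: the spline reproduces polynomials up to cubics
#' @export
notaknot_spline <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (any(duplicated(x))) stop("duplicate x values")
  o <- order(x); x <- as.numeric(x[o]); y <- as.numeric(y[o])
  M <- .nak_moments(x, y)
  h <- diff(x)
  n <- length(x)

  piece_value <- function(i, t) {
    # t in [0, h_i], offset from x_i
    hi <- h[i]
    a <- (x[i + 1] - (x[i] + t)) / hi
    b <- t / hi
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * hi^2 / 6
  }
  piece_integral <- function(i, t0, t1) {
    # antiderivative of piece i, evaluated between offsets t0 and t1
    hi <- h[i]
    F <- function(t) {
      a <- (hi - t) / hi; b <- t / hi
      -hi * a^2 / 2 * y[i] + hi * b^2 / 2 * y[i + 1] +
        hi^2 / 6 * (M[i] * (-hi) * (a^4 / 4 - a^2 / 2) +
                    M[i + 1] * hi * (b^4 / 4 - b^2 / 2))
    }
    F(t1) - F(t0)
  }

  predict <- function(xx) {
    vapply(xx, function(p) {
      if (p < x[1] || p > x[n]) stop("evaluation outside knot range")
      i <- max(1, min(n - 1, findInterval(p, x, rightmost.closed = TRUE)))
      piece_value(i, p - x[i])
    }, numeric(1))
  }
  integral <- function(a = x[1], b = x[n]) {
    if (a > b) return(-integral(b, a))
    if (a < x[1] || b > x[n]) stop("integration limits outside knot range")
    tot <- 0
    for (i in seq_len(n - 1)) {
      lo <- max(a, x[i]); hi_ <- min(b, x[i + 1])
      if (hi_ > lo) tot <- tot + piece_integral(i, lo - x[i], hi_ - x[i])
    }
    tot
  }
  list(predict = predict, integral = integral, knots = x, moments = M)
}
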