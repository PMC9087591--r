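## Free-energy estimators: Bennett acceptance ratio, exponential (Zwanzig)
## averaging, finite-difference TI derivatives, and quadrature of derivative
## profiles.

#' Free energy by exponential (Zwanzig) averaging
#'
#' One-sided free-energy perturbation estimate
#' \eqn{\Delta G = -kT \log \langle e^{-\beta \Delta U} \rangle}.
#'
#' @param du Perturbation energies Delta U, kcal/mol.
#' @param temperature_K Temperature, K.
#' @return Delta G in kcal/mol.
#' @export
zwanzig_dg <- function(du, temperature_K = 295) {
  if (!length(du)) stop("empty sample list")
  if (any(!is.finite(du))) stop("non-finite samples rejected")
  kt <- kT(temperature_K)
  -kt * .log_mean_exp(-du / kt)
}

#' Bennett acceptance ratio (BAR) free-energy estimate
#'
#' Solves Bennett's self-consistent implicit equation for the free-energy
#' difference between two neighbouring lambda states, from forward
#' perturbation energies sampled in the first state and backward
#' perturbation energies sampled in the second. The equation balances
#' Fermi-weighted acceptance sums and is solved by bracketing plus Newton
#' polishing; the reported standard error is the standard asymptotic
#' variance, assuming independent samples (no decorrelation is applied).
#' Exchanging the roles of the two sample sets (the reversed transformation)
#' negates the estimate exactly.
#'
#' @param du_forward Delta U(state 1 -> state 2) sampled in state 1, kcal/mol.
#' @param du_backward Delta U(state 2 -> state 1) sampled in state 2, kcal/mol.
#' @param temperature_K Temperature, K.
#' @param tol Convergence tolerance on Delta G, kcal/mol.
#' @return A [free_energy_estimate()] with method "BAR".
#' @examples
#' bar_estimate(rep(2, 100), rep(-2, 100))   # symmetric case: dG = 2
#' @export
bar_estimate <- function(du_forward, du_backward, temperature_K = 295,
                         tol = 1e-10) {
  if (!length(du_forward) || !length(du_backward))
    stop("no overlap: both forward and backward sample lists must be non-empty")
  if (any(!is.finite(du_forward)) || any(!is.finite(du_backward)))
    stop("non-finite samples rejected")
  kt <- kT(temperature_K)
  beta <- 1 / kt
  nf <- length(du_forward); nr <- length(du_backward)
  lnr <- log(nf / nr)

  fermi <- function(x) 1 / (1 + exp(x))
  # strictly increasing in dG
  g <- function(dG) {
    sum(fermi(beta * (du_forward - dG) + lnr)) -
      sum(fermi(beta * (du_backward + dG) - lnr))
  }

  # bracket around the two one-sided estimates
  lo <- min(zwanzig_dg(du_forward, temperature_K),
            -zwanzig_dg(du_backward, temperature_K)) - 1
  hi <- max(zwanzig_dg(du_forward, temperature_K),
            -zwanzig_dg(du_backward, temperature_K)) + 1
  step <- max(1, hi - lo)
  while (g(lo) > 0) { lo <- lo - step; step <- step * 2 }
  step <- max(1, hi - lo)
  while (g(hi) < 0) { hi <- hi + step; step <- step * 2 }
  dG <- stats::uniroot(g, c(lo, hi), tol = min(tol, 1e-10))$root

  # Newton polish to machine precision (g' > 0 everywhere)
  for (it in 1:5) {
    f1 <- fermi(beta * (du_forward - dG) + lnr)
    f2 <- fermi(beta * (du_backward + dG) - lnr)
    gp <- beta * (sum(f1 * (1 - f1)) + sum(f2 * (1 - f2)))
    if (gp <= 0) break
    upd <- (sum(f1) - sum(f2)) / gp
    dG <- dG + upd
    if (abs(upd) < 1e-14 * max(1, abs(dG))) break
  }

  f1 <- fermi(beta * (du_forward - dG) + lnr)
  f2 <- fermi(beta * (du_backward + dG) - lnr)
  var_beta <- (mean(f1^2) / mean(f1)^2 - 1) / nf +
              (mean(f2^2) / mean(f2)^2 - 1) / nr
  free_energy_estimate(dG, sqrt(max(var_beta, 0)) * kt, "BAR",
                       n_samples = nf + nr)
}

#' Finite-difference TI derivative at one window
#'
#' Estimates dG/dlambda at a window by finite differences of small-step
#' free-energy perturbations: each G(lambda +/- delta) - G(lambda) is
#' obtained by exponential averaging of `du_plus`/`du_minus`, and the
#' derivative is the central difference \eqn{[G(\lambda+\delta) -
#' G(\lambda-\delta)] / (2\delta)}. At the endpoints of the lambda range
#' (or when one side is missing, with a warning) a one-sided difference is
#' used.
#'
#' @param window A [lambda_window()] carrying `du_plus` and/or `du_minus`.
#' @param delta_lambda Small step delta used when the samples were generated.
#' @param temperature_K Temperature, K.
#' @return The derivative in kcal/mol, with attribute `"stderr"` (delta-method
#'   propagation; paired when both sample lists have equal length).
#' @export
fd_ti_derivative <- function(window, delta_lambda = 0.01, temperature_K = 295) {
  stopifnot(inherits(window, "lambda_window"))
  if (delta_lambda <= 0) stop("delta_lambda must be > 0")
  kt <- kT(temperature_K)
  lam <- window$lambda_value
  has_p <- length(window$du_plus) > 0
  has_m <- length(window$du_minus) > 0
  if (!has_p && !has_m)
    stop("window carries neither du_plus nor du_minus samples")
  interior <- lam > 0 && lam < 1

  dg_se <- function(du) {
    a <- exp(-du / kt)
    c(dg = -kt * .log_mean_exp(-du / kt),
      se = kt * stats::sd(a) / (mean(a) * sqrt(length(a))))
  }

  if (has_p && has_m) {
    p <- dg_se(window$du_plus); m <- dg_se(window$du_minus)
    val <- (p["dg"] - m["dg"]) / (2 * delta_lambda)
    if (length(window$du_plus) == length(window$du_minus)) {
      # same frames: propagate the covariance of the two exponential means
      a <- exp(-window$du_plus / kt); b <- exp(-window$du_minus / kt)
      n <- length(a)
      v <- (stats::var(a) / mean(a)^2 + stats::var(b) / mean(b)^2 -
              2 * stats::cov(a, b) / (mean(a) * mean(b))) / n
      se <- kt * sqrt(max(v, 0)) / (2 * delta_lambda)
    } else {
      se <- sqrt(p["se"]^2 + m["se"]^2) / (2 * delta_lambda)
    }
  } else if (has_p) {
    if (interior)
      warning(sprintf("lambda = %g: du_minus missing, one-sided forward difference", lam))
    p <- dg_se(window$du_plus)
    val <- p["dg"] / delta_lambda
    se <- p["se"] / delta_lambda
  } else {
    if (interior)
      warning(sprintf("lambda = %g: du_plus missing, one-sided backward difference", lam))
    m <- dg_se(window$du_minus)
    val <- -m["dg"] / delta_lambda
    se <- m["se"] / delta_lambda
  }
  structure(unname(val), stderr = unname(se))
}

#' TI derivative profile of a run
#'
#' Applies [fd_ti_derivative()] to every window of a run and assembles a
#' [derivative_profile()], with window durations as sampling weights.
#'
#' @param run A [fep_run()].
#' @inheritParams fd_ti_derivative
#' @return A [derivative_profile()].
#' @export
run_derivative_profile <- function(run, delta_lambda = 0.01,
                                   temperature_K = run$temperature_K) {
  stopifnot(inherits(run, "fep_run"))
  ders <- lapply(run$windows, fd_ti_derivative, delta_lambda = delta_lambda,
                 temperature_K = temperature_K)
  derivative_profile(
    lambdas = vapply(run$windows, `[[`, numeric(1), "lambda_value"),
    derivatives = vapply(ders, as.numeric, numeric(1)),
    weights = vapply(run$windows, `[[`, numeric(1), "duration_ns"),
    stderr = vapply(ders, attr, numeric(1), "stderr"))
}

#' Integrate a derivative profile with a not-a-knot cubic spline
#'
#' Interpolates dG/dlambda with a not-a-knot cubic spline and integrates the
#' interpolant in closed form over the profile's lambda range. With only two
#' points it falls back to the trapezoid rule, with a warning.
#'
#' @param profile A [derivative_profile()].
#' @return A [free_energy_estimate()] with method "TI_spline" (stderr
#'   propagated through the quadrature weights when the profile carries
#'   per-point standard errors).
#' @examples
#' p <- derivative_profile(seq(0, 1, 0.25), c(-18.0, -50.3, -79.4, -109.8, -147.5))
#' spline_integrate(p)  # about -80.4 kcal/mol
#' @export
spline_integrate <- function(profile) {
  stopifnot(inherits(profile, "derivative_profile"))
  x <- profile$lambdas; y <- profile$derivatives
  if (any(duplicated(x))) stop("duplicate lambda values")
  if (length(x) < 2) stop("at least 2 points are required")
  if (length(x) == 2) {
    warning("only 2 points: falling back to trapezoid rule")
    return(trapezoid_integrate(profile))
  }
  val <- .nak_integral(x, y)
  se <- NA_real_
  if (!is.null(profile$stderr)) {
    w <- .nak_weights(x)
    se <- sqrt(sum((w * profile$stderr)^2))
  }
  free_energy_estimate(val, se, "TI_spline")
}

#' Trapezoid-rule integration of a derivative profile
#'
#' @inheritParams spline_integrate
#' @return A [free_energy_estimate()] with method "TI_trapezoid".
#' @export
trapezoid_integrate <- function(profile) {
  stopifnot(inherits(profile, "derivative_profile"))
  x <- profile$lambdas; y <- profile$derivatives
  if (length(x) < 2) stop("at least 2 points are required")
  h <- diff(x)
  val <- sum(h * (y[-length(y)] + y[-1]) / 2)
  se <- NA_real_
  if (!is.null(profile$stderr)) {
    w <- c(h / 2, 0) + c(0, h / 2)
    se <- sqrt(sum((w * profile$stderr)^2))
  }
  free_energy_estimate(val, se, "TI_trapezoid")
}

#' Composite Simpson integration of a derivative profile
#'
#' Requires an odd number of equally spaced points.
#'
#' @inheritParams spline_integrate
#' @return A [free_energy_estimate()] with method "TI_simpson".
#' @export
simpson_integrate <- function(profile) {
  stopifnot(inherits(profile, "derivative_profile"))
  x <- profile$lambdas; y <- profile$derivatives
  n <- length(x)
  if (n < 3 || n %% 2 == 0)
    stop("Simpson's rule requires an odd number (>= 3) of points")
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-9 * h[1])
    stop("Simpson's rule requires an equally spaced grid")
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  val <- h[1] / 3 * sum(w * y)
  se <- if (is.null(profile$stderr)) NA_real_ else
    sqrt(sum((h[1] / 3 * w * profile$stderr)^2))
  free_energy_estimate(val, se, "TI_simpson")
}

#' Sum per-window free-energy contributions
#'
#' Arithmetic total of per-interval Delta G values (e.g. BAR contributions
#' for consecutive lambda intervals of one run).
#'
#' @param per_window_dG Numeric vector of window contributions, kcal/mol.
#' @param stderr Optional per-window standard errors (summed in quadrature).
#' @return A [free_energy_estimate()] with method "window_sum".
#' @export
sum_windows <- function(per_window_dG, stderr = NULL) {
  if (!length(per_window_dG)) stop("empty list of window contributions")
  if (any(!is.finite(per_window_dG))) stop("non-finite window contribution")
  se <- if (is.null(stderr)) NA_real_ else sqrt(sum(stderr^2))
  free_energy_estimate(sum(per_window_dG), se, "window_sum")
}

#' BAR estimate over all windows of a run
#'
#' Applies [bar_estimate()] to each adjacent window pair of a run (forward
#' samples of window i against backward samples of window i + 1) and sums
#' the contributions.
#'
#' @param run A [fep_run()] whose windows carry `du_forward`/`du_backward`.
#' @return A [free_energy_estimate()] with method "window_sum"; the
#'   per-interval estimates are attached as attribute `"windows"`.
#' @export
bar_run_total <- function(run) {
  stopifnot(inherits(run, "fep_run"))
  n <- length(run$windows)
  if (n < 2) stop("a run needs at least two windows for BAR")
  ests <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    ests[[i]] <- bar_estimate(run$windows[[i]]$du_forward,
                              run$windows[[i + 1]]$du_backward,
                              run$temperature_K)
  }
  vals <- vapply(ests, `[[`, numeric(1), "value")
  ses <- vapply(ests, `[[`, numeric(1), "stderr")
  out <- sum_windows(vals, stderr = ses)
  attr(out, "windows") <- ests
  out
}
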