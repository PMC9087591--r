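## Containers for alchemical runs: lambda windows, runs, derivative profiles
## and free-energy estimates.

#' Construct a lambda window
#'
#' One window of an alchemical transformation: a value of the coupling
#' variable lambda together with the perturbation-energy samples collected
#' there. `du_forward`/`du_backward` hold Delta U to the neighbouring windows
#' (for BAR); `du_plus`/`du_minus` hold Delta U for small steps lambda +/-
#' delta (for finite-difference thermodynamic integration).
#'
#' @param lambda_value Coupling variable in \[0, 1\].
#' @param duration_ns Simulation length of the window in nanoseconds (> 0).
#'   Used as the sampling weight when profiles from several runs are combined.
#' @param du_forward,du_backward Perturbation energies to the next/previous
#'   window, kcal/mol.
#' @param du_plus,du_minus Small-step perturbation energies to lambda +/-
#'   delta, kcal/mol.
#' @return An object of class `lambda_window`.
#' @export
lambda_window <- function(lambda_value, duration_ns = 1,
                          du_forward = NULL, du_backward = NULL,
                          du_plus = NULL, du_minus = NULL) {
  if (!is.numeric(lambda_value) || length(lambda_value) != 1 ||
      lambda_value < 0 || lambda_value > 1)
    stop("lambda_value must be a single number in [0, 1]")
  if (!is.numeric(duration_ns) || duration_ns <= 0)
    stop("duration_ns must be > 0")
  samples <- list(du_forward = du_forward, du_backward = du_backward,
                  du_plus = du_plus, du_minus = du_minus)
  for (kind in names(samples)) {
    s <- samples[[kind]]
    if (!is.null(s) && (!is.numeric(s) || any(!is.finite(s))))
      stop("non-finite or non-numeric samples in ", kind)
  }
  if (all(vapply(samples, function(s) length(s) == 0, logical(1))))
    stop("at least one sample list must be non-empty")
  structure(c(list(lambda_value = lambda_value, duration_ns = duration_ns),
              samples),
            class = "lambda_window")
}

#' Construct an alchemical run
#'
#' An ordered series of lambda windows belonging to one free-energy run
#' (e.g. one forward or backward pass over the transformation).
#'
#' @param run_id Label for the run (e.g. "A", "A'", "d").
#' @param windows List of [lambda_window()] objects; lambda values must be
#'   distinct. They are sorted into ascending lambda order.
#' @param direction One of "forward", "backward", "partial".
#' @param temperature_K Simulation temperature, K.
#' @return An object of class `fep_run`.
#' @export
fep_run <- function(run_id, windows, direction = c("forward", "backward", "partial"),
                    temperature_K = 295) {
  direction <- match.arg(direction)
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0")
  if (!length(windows) || !all(vapply(windows, inherits, logical(1), "lambda_window")))
    stop("windows must be a non-empty list of lambda_window objects")
  lam <- vapply(windows, `[[`, numeric(1), "lambda_value")
  windows <- windows[order(lam)]
  lam <- sort(lam)
  if (any(diff(lam) <= 0))
    stop("lambda values must be strictly increasing after ordering")
  structure(list(run_id = run_id, direction = direction,
                 windows = windows, temperature_K = temperature_K),
            class = "fep_run")
}

#' @export
print.fep_run <- function(x, ...) {
  lam <- vapply(x$windows, `[[`, numeric(1), "lambda_value")
  cat(sprintf("<fep_run %s> %s, %d windows (lambda %s), T = %g K\n",
              x$run_id, x$direction, length(x$windows),
              paste(format(lam), collapse = ", "), x$temperature_K))
  invisible(x)
}

#' Construct a free-energy derivative profile
#'
#' The thermodynamic-integration integrand: mean dG/dlambda on an ascending
#' lambda grid, optionally with per-point effective sampling weights
#' (nanoseconds) and standard errors.
#'
#' @param lambdas Strictly increasing grid in \[0, 1\].
#' @param derivatives dG/dlambda values, kcal/mol.
#' @param weights Optional per-point sampling weights, ns (> 0).
#' @param stderr Optional per-point standard errors, kcal/mol.
#' @return An object of class `derivative_profile`.
#' @export
derivative_profile <- function(lambdas, derivatives, weights = NULL, stderr = NULL) {
  if (length(lambdas) != length(derivatives))
    stop("lambdas and derivatives must have the same length")
  if (any(!is.finite(lambdas)) || any(!is.finite(derivatives)))
    stop("lambdas and derivatives must be finite")
  if (any(diff(lambdas) <= 0))
    stop("lambdas must be strictly increasing")
  if (!is.null(weights)) {
    if (length(weights) != length(lambdas) || any(weights <= 0))
      stop("weights must be positive and match the grid length")
  }
  if (!is.null(stderr)) {
    if (length(stderr) != length(lambdas) || any(stderr < 0))
      stop("stderr must be non-negative and match the grid length")
  }
  structure(list(lambdas = as.numeric(lambdas),
                 derivatives = as.numeric(derivatives),
                 weights = weights, stderr = stderr),
            class = "derivative_profile")
}

#' @export
print.derivative_profile <- function(x, ...) {
  cat(sprintf("<derivative_profile> %d points on [%g, %g]\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  print(data.frame(lambda = x$lambdas, dG_dlambda = x$derivatives))
  invisible(x)
}

#' Construct a free-energy estimate
#'
#' @param value Free-energy difference, kcal/mol.
#' @param stderr Standard error, kcal/mol (NA when unavailable).
#' @param method One of "BAR", "TI_spline", "TI_trapezoid", "TI_simpson",
#'   "window_sum".
#' @param n_samples Number of samples behind the estimate (NA if not tracked).
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(value, stderr = NA_real_, method, n_samples = NA_integer_) {
  method <- match.arg(method,
                      c("BAR", "TI_spline", "TI_trapezoid", "TI_simpson", "window_sum"))
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(value = value, stderr = stderr, method = method,
                 n_samples = n_samples),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, digits = 4, ...) {
  se <- if (is.na(x$stderr)) "" else sprintf(" +/- %.*g", digits, x$stderr)
  cat(sprintf("dG = %.*f%s kcal/mol  [%s]\n", digits, x$value, se, x$method))
  invisible(x)
}
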