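## Cosine-series torsion energetics: fitting parameters to energy scans,
## Boltzmann sampling on the torsion coordinate, and iterative Boltzmann
## inversion against a target angle distribution. This automates the manual
## adjust-and-resimulate loop used to make a Schiff-base dihedral reproduce
## the angle distribution observed in crystal structures.

.deg2rad <- pi / 180

#' Wrap an angle into [-180, 180)
#'
#' Idempotent; +180 maps to -180 by convention.
#'
#' @param chi Angle(s) in degrees.
#' @return Wrapped angle(s) in degrees.
#' @examples
#' wrap_angle(-210)   # 150
#' wrap_angle(180)    # -180
#' @export
wrap_angle <- function(chi) {
  ((chi + 180) %% 360) - 180
}

#' Construct a cosine torsion series
#'
#' The standard periodic dihedral energy
#' \eqn{E(\chi) = \sum_n K_n (1 + \cos(n\chi - \delta_n)) + c}.
#'
#' @param n Integer periodicities (distinct, positive).
#' @param K Barrier coefficients, kcal/mol.
#' @param delta Phases, degrees.
#' @param offset Constant offset c, kcal/mol.
#' @return An object of class `torsion_series`.
#' @export
torsion_series <- function(n, K, delta = rep(0, length(n)), offset = 0) {
  n <- as.integer(n)
  if (any(n <= 0) || anyDuplicated(n)) stop("periodicities must be distinct positive integers")
  if (length(K) != length(n) || length(delta) != length(n))
    stop("n, K and delta must have equal length")
  if (any(!is.finite(K)) || any(!is.finite(delta))) stop("non-finite parameters")
  structure(list(terms = data.frame(n = n, K = as.numeric(K),
                                    delta = as.numeric(delta)),
                 offset = offset),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat("<torsion_series> E(chi) = sum K_n (1 + cos(n chi - delta_n)) + c\n")
  print(x$terms)
  cat(sprintf("offset c = %.4f kcal/mol\n", x$offset))
  invisible(x)
}

#' Evaluate a torsion energy series
#'
#' @param params A [torsion_series()].
#' @param chi Angle(s) in degrees; the result is 360-degree periodic.
#' @return Energy in kcal/mol.
#' @examples
#' ts <- torsion_series(3, 2)
#' torsion_energy(ts, c(0, 60))   # 4, 0
#' @export
torsion_energy <- function(params, chi) {
  stopifnot(inherits(params, "torsion_series"))
  tm <- params$terms
  out <- rep(params$offset, length(chi))
  for (i in seq_len(nrow(tm))) {
    out <- out + tm$K[i] *
      (1 + cos((tm$n[i] * chi - tm$delta[i]) * .deg2rad))
  }
  out
}

#' Construct a torsion energy scan
#'
#' @param angles Scan angles in degrees (wrapped to \[-180, 180); must be
#'   distinct after wrapping).
#' @param energies Energies, kcal/mol (stored relative to the scan minimum).
#' @return An object of class `torsion_scan`.
#' @export
torsion_scan <- function(angles, energies) {
  if (length(angles) != length(energies)) stop("angles and energies differ in length")
  angles <- wrap_angle(angles)
  if (anyDuplicated(angles)) stop("duplicate scan angles after wrapping")
  if (any(!is.finite(energies))) stop("non-finite scan energies")
  o <- order(angles)
  structure(list(angles = angles[o],
                 energies = energies[o] - min(energies)),
            class = "torsion_scan")
}

#' Fit a cosine series to a torsion energy scan
#'
#' Linear least squares in the parametrization \eqn{a_n = K_n \cos\delta_n},
#' \eqn{b_n = K_n \sin\delta_n} plus a constant, so the fit is exact when the
#' scan lies in the model class.
#'
#' @param scan A [torsion_scan()].
#' @param periodicities Integer set of periodicities to fit (default 1:3).
#' @return List with `series` (a [torsion_series()]) and `residual_rms`
#'   (kcal/mol).
#' @export
fit_cosine_series <- function(scan, periodicities = 1:3) {
  stopifnot(inherits(scan, "torsion_scan"))
  periodicities <- as.integer(periodicities)
  npar <- 2 * length(periodicities) + 1
  if (length(scan$angles) <= npar)
    stop("underdetermined fit: need more scan points than free parameters")
  X <- cbind(1, do.call(cbind, lapply(periodicities, function(n)
    cbind(cos(n * scan$angles * .deg2rad), sin(n * scan$angles * .deg2rad)))))
  fit <- stats::lm.fit(X, scan$energies)
  cf <- fit$coefficients
  a <- cf[seq(2, npar, 2)]
  b <- cf[seq(3, npar, 2)]
  K <- sqrt(a^2 + b^2)
  delta <- wrap_angle(atan2(b, a) / .deg2rad)
  delta[K < 1e-12] <- 0
  series <- torsion_series(periodicities, K, delta,
                           offset = unname(cf[1]) - sum(K))
  list(series = series,
       residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Boltzmann density of a torsion potential
#'
#' Numerically normalized density \eqn{p(\chi) \propto e^{-E(\chi)/kT}} on a
#' uniform circular grid.
#'
#' @param params A [torsion_series()].
#' @param temperature_K Temperature, K.
#' @param n_grid Number of grid points over \[-180, 180).
#' @return Data frame with `chi` (degrees) and `density` (per degree).
#' @export
boltzmann_density <- function(params, temperature_K = 295, n_grid = 720) {
  chi <- seq(-180, 180 - 360 / n_grid, length.out = n_grid)
  e <- torsion_energy(params, chi)
  w <- exp(-(e - min(e)) / kT(temperature_K))
  data.frame(chi = chi, density = w / (sum(w) * 360 / n_grid))
}

#' Construct a circular angle distribution
#'
#' Probability mass per bin over a circular partition of \[-180, 180).
#'
#' @param bin_edges Ascending bin edges in degrees, from -180 to 180.
#' @param masses Probability mass per bin (non-negative, summing to 1).
#' @return An object of class `angle_distribution`.
#' @export
angle_distribution <- function(bin_edges, masses) {
  if (length(bin_edges) != length(masses) + 1) stop("need one more edge than bins")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be ascending")
  if (abs(bin_edges[1] + 180) > 1e-9 || abs(bin_edges[length(bin_edges)] - 180) > 1e-9)
    stop("bin edges must span [-180, 180]")
  if (any(masses < 0)) stop("masses must be >= 0")
  if (abs(sum(masses) - 1) > 1e-9) stop("masses must sum to 1")
  structure(list(bin_edges = bin_edges, masses = masses),
            class = "angle_distribution")
}

#' Histogram angle samples into an angle distribution
#'
#' @param samples Angles in degrees (wrapped internally).
#' @param n_bins Number of equal circular bins (default 20).
#' @return An [angle_distribution()].
#' @export
angle_histogram <- function(samples, n_bins = 20) {
  edges <- seq(-180, 180, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(wrap_angle(samples), edges,
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = n_bins)
  angle_distribution(edges, cnt / sum(cnt))
}

#' Distribution of a torsion potential on given bins
#'
#' Exact (quadrature) Boltzmann probability mass of a torsion series on the
#' bins of an [angle_distribution()] layout.
#'
#' @param params A [torsion_series()].
#' @param bin_edges Ascending circular bin edges spanning \[-180, 180\].
#' @param temperature_K Temperature, K.
#' @param oversample Quadrature points per bin.
#' @return An [angle_distribution()].
#' @export
boltzmann_bin_masses <- function(params, bin_edges, temperature_K = 295,
                                 oversample = 50) {
  n_bins <- length(bin_edges) - 1
  masses <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    chi <- seq(bin_edges[i], bin_edges[i + 1], length.out = oversample + 1)
    chi <- (chi[-1] + chi[-length(chi)]) / 2
    e <- torsion_energy(params, chi)
    masses[i] <- sum(exp(-e / kT(temperature_K))) * diff(bin_edges)[i]
  }
  angle_distribution(bin_edges, masses / sum(masses))
}

#' Overlap between two angle distributions
#'
#' \eqn{\sum_i \min(p_i, q_i)}: 1 for identical distributions, 0 for
#' disjoint ones.
#'
#' @param p,q [angle_distribution()] objects on the same bins.
#' @return Overlap in \[0, 1\].
#' @export
distribution_overlap <- function(p, q) {
  stopifnot(inherits(p, "angle_distribution"), inherits(q, "angle_distribution"))
  if (length(p$masses) != length(q$masses) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-9)
    stop("distributions must share the same bins")
  sum(pmin(p$masses, q$masses))
}

#' Metropolis sampling of a torsion Boltzmann distribution
#'
#' Markov chain on the circular coordinate targeting
#' \eqn{p(\chi) \propto e^{-E(\chi)/kT}}, with symmetric uniform proposals.
#' Deterministic for a given seed.
#'
#' @param params A [torsion_series()].
#' @param temperature_K Temperature, K.
#' @param n_samples Number of retained samples.
#' @param step_deg Proposal half-width, degrees.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @param burn_in Discarded initial steps.
#' @param init Initial angle, degrees.
#' @return Numeric vector of angle samples in \[-180, 180).
#' @export
metropolis_sample <- function(params, temperature_K = 295, n_samples = 10000,
                              step_deg = 30, seed = NULL, burn_in = 1000,
                              init = 0) {
  stopifnot(inherits(params, "torsion_series"))
  if (n_samples <= 0) stop("n_samples must be > 0")
  if (!is.null(seed)) set.seed(seed)
  kt <- kT(temperature_K)
  tm <- params$terms
  energy <- function(x) sum(tm$K * (1 + cos((tm$n * x - tm$delta) * .deg2rad)))
  total <- burn_in + n_samples
  steps <- stats::runif(total, -step_deg, step_deg)
  accept_u <- stats::runif(total)
  out <- numeric(n_samples)
  x <- wrap_angle(init)
  e <- energy(x)
  for (t in seq_len(total)) {
    xp <- wrap_angle(x + steps[t])
    ep <- energy(xp)
    if (ep <= e || accept_u[t] < exp(-(ep - e) / kt)) {
      x <- xp; e <- ep
    }
    if (t > burn_in) out[t - burn_in] <- x
  }
  out
}

#' Match a torsion potential to a target angle distribution
#'
#' Iterative Boltzmann inversion (IBI): at each iteration the current model
#' is sampled with [metropolis_sample()], the tabulated potential at the bin
#' centers is updated by \eqn{+\alpha\, kT \ln(p_{current}/p_{target})}, and
#' the cosine series is refit to the updated table. The series whose
#' sampled distribution best overlaps the target is returned. This is the
#' automated analogue of manually adjusting dihedral parameters until
#' simulations reproduce an experimentally inferred angle distribution.
#'
#' @param initial Starting [torsion_series()].
#' @param target Target [angle_distribution()] (empty bins are floored).
#' @param temperature_K Temperature, K.
#' @param iterations Maximum IBI iterations.
#' @param damping Update damping factor alpha in (0, 1\].
#' @param n_samples Metropolis samples per iteration.
#' @param step_deg Metropolis proposal half-width, degrees.
#' @param seed Integer seed controlling the whole refinement.
#' @param prob_floor Probability floor per bin, regularizing the log ratio.
#' @param periodicities Periodicities used in the refits (defaults to those
#'   of `initial`, or 1:3 when `initial` has none).
#' @return The best [torsion_series()], with attributes `"overlap"` (its
#'   overlap with the target) and `"history"` (per-iteration overlaps).
#' @export
match_distribution <- function(initial, target, temperature_K = 295,
                               iterations = 15, damping = 0.5,
                               n_samples = 20000, step_deg = 30, seed = 1,
                               prob_floor = 1e-4, periodicities = NULL) {
  stopifnot(inherits(initial, "torsion_series"),
            inherits(target, "angle_distribution"))
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  if (is.null(periodicities)) {
    periodicities <- initial$terms$n
    if (!length(periodicities)) periodicities <- 1:3
  }
  kt <- kT(temperature_K)
  edges <- target$bin_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  p_tgt <- pmax(target$masses, prob_floor)
  p_tgt <- p_tgt / sum(p_tgt)

  if (!is.null(seed)) set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, iterations)

  current <- initial
  best <- initial
  best_overlap <- -Inf
  history <- numeric(0)
  decreasing <- 0
  for (it in seq_len(iterations)) {
    samp <- metropolis_sample(current, temperature_K, n_samples, step_deg,
                              seed = iter_seeds[it])
    hist_cur <- angle_histogram(samp, n_bins = length(centers))
    ov <- distribution_overlap(hist_cur, angle_distribution(edges, p_tgt))
    history <- c(history, ov)
    if (ov > best_overlap) {
      best_overlap <- ov
      best <- current
    }
    if (it > 1 && history[it] < history[it - 1]) {
      decreasing <- decreasing + 1
      if (decreasing >= 3) {
        warning(sprintf(
          "overlap decreased 3 consecutive iterations (last %.4f); aborting refinement",
          ov))
        break
      }
    } else decreasing <- 0

    p_cur <- pmax(hist_cur$masses, prob_floor)
    p_cur <- p_cur / sum(p_cur)
    v_tab <- torsion_energy(current, centers) +
      damping * kt * log(p_cur / p_tgt)
    refit <- fit_cosine_series(torsion_scan(centers, v_tab),
                               periodicities = periodicities)
    current <- refit$series
  }
  structure(best, overlap = best_overlap, history = history)
}

#' Render a torsion series as a force-field dihedral stanza
#'
#' Formats one line per cosine term in the conventional dihedral-parameter
#' layout (atom-type quadruple, K_n, n, delta_n).
#'
#' @param params A [torsion_series()].
#' @param atom_types Character vector of four atom types (default the
#'   Schiff-base quadruple C4 C4A NZ CE).
#' @return Character vector of stanza lines.
#' @export
as_dihedral_stanza <- function(params, atom_types = c("C4", "C4A", "NZ", "CE")) {
  stopifnot(inherits(params, "torsion_series"), length(atom_types) == 4)
  tm <- params$terms
  vapply(seq_len(nrow(tm)), function(i)
    sprintf("%-4s %-4s %-4s %-4s %10.5f %3d %10.3f",
            atom_types[1], atom_types[2], atom_types[3], atom_types[4],
            tm$K[i], tm$n[i], tm$delta[i]),
    character(1))
}
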