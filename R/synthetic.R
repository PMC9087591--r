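## Seeded synthetic-data generators with known ground truth, standing in for
## the MD trajectories and QM scans consumed by the analysis modules. Every
## generator records its seed and its analytic ground truth alongside the
## data, so downstream tests never re-derive either.

#' Ground truth of a generated object
#'
#' @param x A generated object.
#' @return The `ground_truth` list recorded by the generator.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

.with_truth <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Generate Crooks-Gaussian work samples
#'
#' Forward work ~ Normal(dG + beta sigma^2/2, sigma^2) and backward work ~
#' Normal(-dG + beta sigma^2/2, sigma^2). This pair satisfies the Crooks
#' fluctuation relation exactly, so the BAR estimand equals `true_dG`.
#'
#' @param true_dG Ground-truth free-energy difference, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol (> 0).
#' @param n Samples per direction (> 0).
#' @param temperature_K Temperature, K.
#' @param seed Integer seed.
#' @return List with `du_forward` and `du_backward`; ground truth retrievable
#'   with [ground_truth()].
#' @export
gen_crooks_gaussian <- function(true_dG, sigma, n, temperature_K = 295, seed = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (n <= 0) stop("n must be > 0")
  set.seed(seed)
  beta <- 1 / kT(temperature_K)
  mu_f <- true_dG + beta * sigma^2 / 2
  mu_r <- -true_dG + beta * sigma^2 / 2
  out <- list(du_forward = stats::rnorm(n, mu_f, sigma),
              du_backward = stats::rnorm(n, mu_r, sigma))
  .with_truth(out, list(kind = "crooks_gaussian", true_dG = true_dG,
                        sigma = sigma, n = n, temperature_K = temperature_K,
                        forward_mean = mu_f, backward_mean = mu_r,
                        seed = seed, rng = RNGkind()[1]))
}

#' Generate a harmonic-alchemy FEP run
#'
#' An exactly solvable alchemical transformation: a single harmonic
#' coordinate with U(x; lambda) = (1/2) k(lambda) x^2 and k(lambda) = k0 +
#' lambda (k1 - k0). Frames are exact equilibrium draws at each lambda (or
#' AR(1)-correlated draws when `rho` > 0) and per-frame perturbation
#' energies to the neighbouring windows and to lambda +/- delta are emitted,
#' so both BAR and finite-difference TI can be run end-to-end. The analytic
#' total is \eqn{\Delta G = (kT/2) \ln(k_1/k_0)}.
#'
#' @param k0,k1 Endpoint force constants, kcal/mol/A^2 (> 0).
#' @param lambda_grid Window lambda values (default 0, 0.25, ..., 1).
#' @param n_frames Frames per window.
#' @param temperature_K Temperature, K.
#' @param delta_lambda Small step for the TI samples.
#' @param rho AR(1) frame autocorrelation (0 = independent draws).
#' @param seed Integer seed.
#' @return A [fep_run()]; [ground_truth()] carries the analytic total and
#'   the analytic derivative at each lambda.
#' @export
gen_harmonic_alchemy <- function(k0, k1, lambda_grid = seq(0, 1, 0.25),
                                 n_frames = 1000, temperature_K = 295,
                                 delta_lambda = 0.01, rho = 0, seed = 1) {
  if (k0 <= 0 || k1 <= 0) stop("force constants must be > 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  set.seed(seed)
  kt <- kT(temperature_K)
  kfun <- function(l) k0 + l * (k1 - k0)
  nw <- length(lambda_grid)
  windows <- vector("list", nw)
  for (i in seq_len(nw)) {
    l <- lambda_grid[i]
    sd_x <- sqrt(kt / kfun(l))
    z <- stats::rnorm(n_frames)
    if (rho > 0) {
      x <- numeric(n_frames)
      x[1] <- z[1]
      for (t in 2:n_frames) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * z[t]
      x <- x * sd_x
    } else x <- z * sd_x
    x2h <- x^2 / 2
    du <- function(lp) if (lp < 0 || lp > 1) NULL else (kfun(lp) - kfun(l)) * x2h
    windows[[i]] <- lambda_window(
      lambda_value = l, duration_ns = 1,
      du_forward  = if (i < nw) du(lambda_grid[i + 1]) else NULL,
      du_backward = if (i > 1) du(lambda_grid[i - 1]) else NULL,
      du_plus  = du(l + delta_lambda),
      du_minus = du(l - delta_lambda))
  }
  run <- fep_run("harmonic", windows, direction = "forward",
                 temperature_K = temperature_K)
  .with_truth(run, list(kind = "harmonic_alchemy",
                        true_dG = kt / 2 * log(k1 / k0),
                        derivative = kt / 2 * (k1 - k0) / kfun(lambda_grid),
                        lambda_grid = lambda_grid, k0 = k0, k1 = k1,
                        n_frames = n_frames, temperature_K = temperature_K,
                        rho = rho, seed = seed, rng = RNGkind()[1]))
}

#' Generate noisy polynomial derivative profiles
#'
#' Pseudo-run derivative profiles with a polynomial ground truth:
#' dG/dlambda = sum c_j lambda^j plus Gaussian noise per point and run.
#'
#' @param coefficients Polynomial coefficients c_0, c_1, ... (ascending
#'   degree).
#' @param noise_sd Noise standard deviation, kcal/mol.
#' @param grid Lambda grid in \[0, 1\].
#' @param n_runs Number of pseudo-runs.
#' @param weight_ns Sampling weight assigned to every point.
#' @param seed Integer seed.
#' @return Named list of [derivative_profile()] objects ("run1", ...);
#'   [ground_truth()] carries the analytic integral over \[0, 1\].
#' @export
gen_profile <- function(coefficients, noise_sd = 0, grid = seq(0, 1, 0.25),
                        n_runs = 1, weight_ns = 40, seed = 1) {
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  set.seed(seed)
  j <- seq_along(coefficients) - 1
  truth_fun <- function(l) vapply(l, function(li) sum(coefficients * li^j), numeric(1))
  runs <- stats::setNames(lapply(seq_len(n_runs), function(r)
    derivative_profile(grid,
                       truth_fun(grid) + stats::rnorm(length(grid), 0, noise_sd),
                       weights = rep(weight_ns, length(grid)))),
    paste0("run", seq_len(n_runs)))
  .with_truth(runs, list(kind = "profile_noise",
                         integral_01 = sum(coefficients / (j + 1)),
                         derivative = truth_fun(grid),
                         coefficients = coefficients, noise_sd = noise_sd,
                         seed = seed, rng = RNGkind()[1]))
}

## place atom D given positions A, B, C, bond |CD|, angle BCD (deg),
## dihedral ABCD (deg)  -- standard internal-coordinate construction
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  cross <- function(u, v) c(u[2]*v[3] - u[3]*v[2],
                            u[3]*v[1] - u[1]*v[3],
                            u[1]*v[2] - u[2]*v[1])
  unit <- function(v) v / sqrt(sum(v^2))
  bc <- unit(C - B)
  n <- unit(cross(B - A, bc))
  m <- cross(n, bc)
  ang <- angle * .deg2rad; dih <- dihedral * .deg2rad
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate a toy Schiff-base structure
#'
#' Builds a minimal active-site model around the PLP-lysine Schiff base:
#' ring atoms C5, C4, the bridge C4A, the lysine NZ and CE, placed so that
#' the chi = C4-C4A-NZ-CE dihedral equals the requested value to 1e-6
#' degree. Additional probe atoms are placed at exact requested distances.
#'
#' @param chi Schiff-base dihedral, degrees.
#' @param key_distances Named numeric vector `c("NZ-O3" = 2.9, ...)`: each
#'   name is "REF-NEW" and the NEW atom is placed at exactly that distance
#'   from the REF atom (direction chosen deterministically from `seed`).
#' @param model_id Model label.
#' @param seed Integer seed (placement directions of probe atoms).
#' @return A [structure_model()]; [ground_truth()] records the requested
#'   geometry.
#' @export
gen_toy_structure <- function(chi, key_distances = c("NZ-O3" = 2.9),
                              model_id = "toy", seed = 1) {
  chi <- wrap_angle(chi)
  set.seed(seed)
  C4 <- c(0, 0, 0)
  C4A <- c(1.47, 0, 0)
  NZ <- .place_atom(c(-0.5, 1.2, 0), C4, C4A, 1.28, 121, 35)
  CE <- .place_atom(C4, C4A, NZ, 1.47, 118, chi)
  C5 <- .place_atom(NZ, C4A, C4, 1.40, 120, 155)
  coords <- list(C5 = C5, C4 = C4, C4A = C4A, NZ = NZ, CE = CE)
  resno <- c(C5 = 1, C4 = 1, C4A = 1, NZ = 2, CE = 2)
  resname <- c(C5 = "PLP", C4 = "PLP", C4A = "PLP", NZ = "LYS", CE = "LYS")
  if (length(key_distances)) {
    for (nm in names(key_distances)) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
      if (length(pair) != 2) stop("key_distances names must be 'REF-NEW'")
      ref <- coords[[pair[1]]]
      if (is.null(ref)) stop("unknown reference atom: ", pair[1])
      d <- key_distances[[nm]]
      if (d <= 0) stop("distances must be positive")
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      coords[[pair[2]]] <- ref + d * u
      resno[pair[2]] <- 3
      resname[pair[2]] <- "PRB"
    }
  }
  atoms <- data.frame(atom = names(coords),
                      resname = resname[names(coords)],
                      resno = resno[names(coords)],
                      chain = "A",
                      x = vapply(coords, `[`, numeric(1), 1),
                      y = vapply(coords, `[`, numeric(1), 2),
                      z = vapply(coords, `[`, numeric(1), 3),
                      occupancy = 1,
                      row.names = NULL)
  m <- structure_model(atoms, model_id = model_id)
  .with_truth(m, list(kind = "toy_structure", chi = chi,
                      key_distances = key_distances, seed = seed,
                      rng = RNGkind()[1]))
}

#' Generate a toy ensemble of Schiff-base monomers
#'
#' A batch of toy monomers whose chi angles are drawn around the two
#' crystallographic peak centers with prescribed mixture fractions, and
#' whose NZ-O3 distances encode prescribed A/B orientation labels.
#'
#' @param n Number of monomers (default 63).
#' @param peak_fractions Mixture fractions for the two chi peaks (default
#'   3:1).
#' @param centers Peak centers in degrees (default +150 and -130).
#' @param spread Half-width of the uniform jitter around each center, degrees.
#' @param frac_A Fraction of monomers in the "A" orientation (NZ-O3 bonded).
#' @param seed Integer seed.
#' @return List of [structure_model()] objects; [ground_truth()] carries the
#'   per-monomer chi, peak and orientation labels.
#' @export
gen_toy_ensemble <- function(n = 63, peak_fractions = c(0.75, 0.25),
                             centers = c(150, -130), spread = 15,
                             frac_A = 0.8, seed = 1) {
  stopifnot(length(peak_fractions) == 2, length(centers) == 2)
  peak_fractions <- peak_fractions / sum(peak_fractions)
  set.seed(seed)
  n1 <- round(n * peak_fractions[1])
  peak <- rep(c("peak1", "peak2"), c(n1, n - n1))
  chi <- wrap_angle(ifelse(peak == "peak1", centers[1], centers[2]) +
                      stats::runif(n, -spread, spread))
  nA <- round(n * frac_A)
  orientation <- sample(rep(c("A", "B"), c(nA, n - nA)))
  d_nz_o3 <- ifelse(orientation == "A",
                    stats::runif(n, 2.7, 3.2), stats::runif(n, 4.0, 5.0))
  seeds <- sample.int(.Machine$integer.max, n)
  models <- lapply(seq_len(n), function(i)
    gen_toy_structure(chi[i], key_distances = c("NZ-O3" = d_nz_o3[i]),
                      model_id = sprintf("monomer%02d", i), seed = seeds[i]))
  .with_truth(models,
              list(kind = "toy_ensemble",
                   table = data.frame(model_id = sprintf("monomer%02d", seq_len(n)),
                                      chi = chi, peak = peak,
                                      orientation = orientation,
                                      nz_o3 = d_nz_o3),
                   seed = seed, rng = RNGkind()[1]))
}

#' Generate a synthetic electrostatic potential grid
#'
#' Scalar grid whose values come from a supplied profile function of the
#' Cartesian coordinates (default: a constant bulk value), emulating
#' PME-derived potential maps.
#'
#' @param profile_fn Function taking an n x 3 coordinate matrix and returning
#'   n potential values; NULL means constant `bulk_value`.
#' @param dims Grid point counts per axis.
#' @param spacing Grid spacing, Angstrom.
#' @param origin Grid origin, Angstrom.
#' @param bulk_value Constant used when `profile_fn` is NULL (kcal/mol/e).
#' @param seed Integer seed (recorded; draws only if `profile_fn` uses RNG).
#' @return A [potential_grid()]; [ground_truth()] records the construction.
#' @export
gen_potential_grid <- function(profile_fn = NULL, dims = c(10, 10, 10),
                               spacing = 1, origin = c(0, 0, 0),
                               bulk_value = -2.9, seed = 1) {
  set.seed(seed)
  g <- potential_grid(array(0, dims), origin = origin, spacing = spacing)
  pts <- .grid_coords(g)
  vals <- if (is.null(profile_fn)) rep(bulk_value, nrow(pts)) else profile_fn(pts)
  g$values <- array(vals, dims)
  .with_truth(g, list(kind = "potential_grid", bulk_value = bulk_value,
                      constant = is.null(profile_fn), seed = seed,
                      rng = RNGkind()[1]))
}
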