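## Finite-size corrections for charged alchemical transformations under
## periodic boundary conditions: the bulk-region mean-potential shift imposed
## by PME's zero-mean convention, and the dielectric-scaled periodic
## self-energy of the inserted charge.

#' Construct an electrostatic potential grid
#'
#' A uniform rectilinear scalar grid of the instantaneous (or time-averaged)
#' electrostatic potential over a periodic simulation box, as produced by
#' PME post-processing tools.
#'
#' @param values 3-d array of potential values, kcal/mol/e.
#' @param origin Cartesian origin of the grid, Angstrom (length 3).
#' @param spacing Grid spacing per axis, Angstrom (length 3, or scalar).
#' @param box_vectors 3x3 matrix of periodic cell vectors (rows), Angstrom.
#'   Defaults to the orthorhombic box spanned by the grid.
#' @return An object of class `potential_grid`.
#' @export
potential_grid <- function(values, origin = c(0, 0, 0), spacing = 1,
                           box_vectors = NULL) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3-d array")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (length(origin) != 3) stop("origin must have length 3")
  if (is.null(box_vectors)) box_vectors <- diag(dim(values) * spacing)
  if (!all(dim(box_vectors) == c(3, 3))) stop("box_vectors must be 3x3")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values),
                 box_vectors = box_vectors),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid> %s points, spacing %s A, origin (%s)\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = "/"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

## n x 3 matrix of Cartesian grid-point coordinates
.grid_coords <- function(grid) {
  d <- grid$dims
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                               j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  sweep(ijk %*% diag(grid$spacing), 2, grid$origin, "+")
}

#' Bulk-solvent region mask of a potential grid
#'
#' Marks grid points whose minimum-image distance to every protein atom
#' exceeds `cutoff` as bulk-solvent-like. These points probe the mean
#' potential far from the protein, which PME constrains only through the
#' box-wide zero-mean convention.
#'
#' @param grid A [potential_grid()].
#' @param protein_coords n x 3 matrix of protein atom coordinates, Angstrom,
#'   in the same frame as the grid.
#' @param cutoff Distance cutoff in Angstrom (default 12).
#' @return List with `mask` (logical array over the grid), `n_bulk` and
#'   `n_total`.
#' @export
bulk_region_mask <- function(grid, protein_coords, cutoff = 12) {
  stopifnot(inherits(grid, "potential_grid"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  pts <- .grid_coords(grid)
  if (is.null(protein_coords) || !NROW(protein_coords)) {
    warning("no protein atoms given: the whole grid is classified as bulk")
    mask <- array(TRUE, grid$dims)
    return(list(mask = mask, n_bulk = length(mask), n_total = length(mask)))
  }
  protein_coords <- matrix(as.numeric(protein_coords), ncol = 3)
  A <- grid$box_vectors
  Ainv <- solve(A)
  mind2 <- rep(Inf, nrow(pts))
  for (a in seq_len(nrow(protein_coords))) {
    dv <- sweep(pts, 2, protein_coords[a, ], "-")
    frac <- dv %*% Ainv
    frac <- frac - round(frac)        # minimum image in fractional coords
    dv <- frac %*% A
    mind2 <- pmin(mind2, rowSums(dv^2))
  }
  mask <- array(mind2 > cutoff^2, grid$dims)
  n_bulk <- sum(mask)
  if (n_bulk == 0)
    warning("cutoff leaves no bulk grid points (degenerate mask)")
  list(mask = mask, n_bulk = n_bulk, n_total = length(mask))
}

#' Mean bulk electrostatic potential
#'
#' Average of the masked grid values over all snapshots. Linear averaging
#' makes per-snapshot masking and time-averaged-grid masking equivalent.
#'
#' @param grids A [potential_grid()] or list of them (MD snapshots), all on
#'   the same grid.
#' @param mask Logical array (or the list returned by [bulk_region_mask()]).
#' @return Mean potential Phi in kcal/mol/e.
#' @export
mean_bulk_potential <- function(grids, mask) {
  if (inherits(grids, "potential_grid")) grids <- list(grids)
  if (!length(grids)) stop("at least one grid is required")
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  if (!any(mask)) stop("empty bulk mask")
  mean(vapply(grids, function(g) {
    stopifnot(inherits(g, "potential_grid"))
    if (!all(g$dims == dim(mask))) stop("mask and grid dimensions differ")
    mean(g$values[mask])
  }, numeric(1)))
}

#' Potential-shift contribution to a charging free energy
#'
#' Under PME the box-mean potential is pinned to zero; upshifting the protein
#' box so that its bulk-solvent region matches the solution system adds
#' \eqn{q \Phi} to the free energy of a transformation that changes the net
#' charge by `q_removed` (+1 e for a deprotonation).
#'
#' @param phi_bulk Mean bulk potential Phi, kcal/mol/e.
#' @param q_removed Charge change of the transformation, e.
#' @return Correction in kcal/mol, to be added to the uncorrected Delta G.
#' @examples
#' -78.3 + shift_correction(-2.9, 1)   # corrected total: -81.2
#' @export
shift_correction <- function(phi_bulk, q_removed = 1) {
  q_removed * phi_bulk
}

#' Cubic periodic cell
#' @param L Edge length, Angstrom.
#' @return 3x3 matrix of cell vectors (rows).
#' @export
cubic_cell <- function(L) diag(rep(L, 3))

#' Truncated-octahedral periodic cell
#'
#' The body-centered-cubic lattice whose Wigner-Seitz cell is the truncated
#' octahedron, parameterized by the circumscribing cube edge `L`.
#'
#' @param L Edge of the circumscribing cube, Angstrom.
#' @return 3x3 matrix of cell vectors (rows).
#' @export
truncated_octahedral_cell <- function(L) {
  rbind(c(L, 0, 0), c(0, L, 0), c(L / 2, L / 2, L / 2))
}

#' Periodic (Wigner) self-energy of a point charge
#'
#' Interaction energy of a point charge with its own periodic images and the
#' uniform neutralizing background, computed by Ewald summation for an
#' arbitrary periodic cell. For a cubic cell of edge L this equals
#' \eqn{k_e \xi q^2 / (2L)} with the Wigner constant \eqn{\xi = -2.837297};
#' it is negative for any non-zero charge and scales as 1/L.
#'
#' @param box_vectors 3x3 matrix of cell vectors (rows), or a scalar edge
#'   length for a cubic cell.
#' @param q Inserted charge, e.
#' @param alpha Ewald splitting parameter, 1/Angstrom. Default 5.6 divided by
#'   the shortest image distance; the result is invariant to this choice.
#' @param real_shells,recip_shells Summation ranges (integer image indices);
#'   the defaults converge to better than 1e-6 relative.
#' @return Self-energy Delta U_self in kcal/mol.
#' @examples
#' ewald_self_energy(78, q = 1)   # about -6.04 kcal/mol
#' @export
ewald_self_energy <- function(box_vectors, q = 1, alpha = NULL,
                              real_shells = 3, recip_shells = 8) {
  if (is.numeric(box_vectors) && length(box_vectors) == 1)
    box_vectors <- cubic_cell(box_vectors)
  A <- as.matrix(box_vectors)
  if (!all(dim(A) == c(3, 3))) stop("box_vectors must be 3x3 or a scalar edge")
  V <- abs(det(A))
  if (V <= 0) stop("singular periodic cell")
  if (q == 0) return(0)

  nmax <- real_shells
  n <- as.matrix(expand.grid(-nmax:nmax, -nmax:nmax, -nmax:nmax))
  n <- n[rowSums(abs(n)) > 0, , drop = FALSE]
  r <- sqrt(rowSums((n %*% A)^2))
  Lmin <- min(r)
  if (is.null(alpha)) alpha <- 5.6 / Lmin
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  real_sum <- sum(erfc(alpha * r) / r)

  B <- 2 * pi * t(solve(A))              # reciprocal vectors (rows)
  m <- as.matrix(expand.grid(-recip_shells:recip_shells,
                             -recip_shells:recip_shells,
                             -recip_shells:recip_shells))
  m <- m[rowSums(abs(m)) > 0, , drop = FALSE]
  k2 <- rowSums((m %*% B)^2)
  recip_sum <- 4 * pi / V * sum(exp(-k2 / (4 * alpha^2)) / k2)

  xi_over_L <- real_sum + recip_sum - 2 * alpha / sqrt(pi) - pi / (alpha^2 * V)
  .ke * q^2 / 2 * xi_over_L
}

#' Dielectric-scaled finite-size self-energy correction
#'
#' The extrapolation to an infinite box adds \eqn{\Delta U_{self} /
#' \epsilon_{box}} to the finite-box free energy, where the box dielectric
#' scales the vacuum periodic self-energy.
#'
#' @param u_self Periodic self-energy, kcal/mol (see [ewald_self_energy()]).
#' @param eps_box Effective box dielectric constant (>= 1).
#' @return Correction in kcal/mol.
#' @examples
#' dielectric_scaled_correction(6.8, 40)   # 0.17 kcal/mol
#' @export
dielectric_scaled_correction <- function(u_self, eps_box) {
  if (eps_box < 1) stop("eps_box must be >= 1")
  u_self / eps_box
}

#' Effective box dielectric from solvent fraction
#'
#' Volume-weighted arithmetic mean of the solvent and protein dielectric
#' constants, \eqn{f \epsilon_w + (1 - f) \epsilon_p}.
#'
#' @param fraction_solvent Solvent volume fraction in \[0, 1\].
#' @param eps_protein Protein-region dielectric (default 20).
#' @param eps_water Water dielectric (default 78.5 at 295 K).
#' @return Effective dielectric, dimensionless.
#' @export
eps_box_estimate <- function(fraction_solvent, eps_protein = 20, eps_water = 78.5) {
  if (fraction_solvent < 0 || fraction_solvent > 1)
    stop("fraction_solvent must be in [0, 1]")
  fraction_solvent * eps_water + (1 - fraction_solvent) * eps_protein
}
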