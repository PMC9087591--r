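## Geometric analysis of active-site ensembles: dihedrals, distances,
## hydrogen-bond occupancies, Schiff-base NZ orientation classes, chi peak
## assignment and per-monomer variable tables.

#' Construct a structure model
#'
#' A minimal atomic model: one row per atom with naming, coordinates and
#' occupancy. `(chain, resno, atom)` must be unique within a model.
#'
#' @param atoms Data frame with columns `atom`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z` and optionally `occupancy` (default 1) and `element`.
#' @param model_id Label for the model/monomer.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model") {
  req <- c("atom", "resname", "resno", "chain", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$element)) atoms$element <- substr(trimws(atoms$atom), 1, 1)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom) entries: ", key[anyDuplicated(key)])
  structure(list(atoms = as.data.frame(atoms), model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s> %d atoms, %d residues\n", x$model_id,
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

## xyz of one atom (or NULL when absent)
.atom_xyz <- function(model, chain, resno, atom) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & trimws(a$atom) == atom)
  if (!length(i)) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking from the second to the third point, a clockwise
#' rotation of the far bond relative to the near bond is positive. Returns
#' degrees in \[-180, 180).
#'
#' @param p1,p2,p3,p4 Cartesian coordinates (length-3 vectors), Angstrom.
#' @return Dihedral angle in degrees.
#' @examples
#' dihedral_angle(c(0,0,1), c(0,0,0), c(1,0,0), c(1,1,0))   # -90
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  cross <- function(u, v) c(u[2]*v[3] - u[3]*v[2],
                            u[3]*v[1] - u[1]*v[3],
                            u[1]*v[2] - u[2]*v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate geometry: collinear triple")
  ub2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * ub2)
  wrap_angle(atan2(y, x) / .deg2rad)
}

#' Euclidean distance between two atoms
#'
#' @param a,b Cartesian coordinates (length-3 vectors), Angstrom.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  sqrt(sum((a - b)^2))
}

#' Contact occupancy of a distance series
#'
#' Fraction of ensemble members (frames or monomers) whose distance is at or
#' under the cutoff. Missing values (e.g. disordered loops) are excluded
#' from the denominator by default.
#'
#' @param distances Numeric distances, Angstrom (may contain NA).
#' @param cutoff Contact cutoff, Angstrom.
#' @param na.rm Drop missing entries from the denominator (default TRUE).
#' @return Occupancy fraction in \[0, 1\].
#' @export
contact_occupancy <- function(distances, cutoff, na.rm = TRUE) {
  if (!length(distances)) stop("empty distance series")
  if (na.rm) distances <- distances[!is.na(distances)]
  if (!length(distances)) stop("no non-missing distances")
  mean(distances <= cutoff)
}

#' Classify the Schiff-base NZ orientation
#'
#' Orientation "A" points the linking NZ atom toward the anion site, where
#' it hydrogen bonds to the phenolic O3 oxygen; "B" has NZ turned inwards,
#' too far from O3 to bond. Classification is by the NZ-O3 heavy-atom
#' distance alone (closed interval at the cutoff); the accompanying dihedral
#' is carried through for reporting only.
#'
#' @param nz_o3_dist NZ-O3 distance(s), Angstrom.
#' @param c5_c4_c4p_nz Optional C5-C4-C4'-NZ dihedral(s), degrees (reported,
#'   not used for classification).
#' @param hbond_cutoff Hydrogen-bond heavy-atom cutoff, Angstrom (default 3.5).
#' @return Data frame with `orientation` ("A"/"B"), the inputs, and the
#'   cutoff used.
#' @export
classify_nz_orientation <- function(nz_o3_dist, c5_c4_c4p_nz = NA_real_,
                                    hbond_cutoff = 3.5) {
  data.frame(orientation = ifelse(nz_o3_dist <= hbond_cutoff, "A", "B"),
             nz_o3_dist = nz_o3_dist,
             c5_c4_c4p_nz = c5_c4_c4p_nz,
             hbond_cutoff = hbond_cutoff)
}

#' Assign a Schiff-base chi angle to its distribution peak
#'
#' The chi = C4-C4'-NZ-CE dihedral observed in crystal structures falls in
#' two peaks centered at +150 deg (= -210 deg) and -130 deg. Peak boundaries
#' are the circular midpoints of the centers: +10 deg and -170 deg.
#'
#' @param chi Angle(s) in degrees (wrapped internally).
#' @return Character vector "peak1" (the +150 peak) or "peak2" (the -130
#'   peak); every angle belongs to exactly one peak.
#' @examples
#' chi_peak_assignment(c(150, -130, -210))   # peak1, peak2, peak1
#' @export
chi_peak_assignment <- function(chi) {
  w <- wrap_angle(chi)
  ifelse(w >= 10 | w < -170, "peak1", "peak2")
}

#' Per-monomer structural variable table
#'
#' Evaluates named geometric variables (distances for 2-atom specs,
#' dihedrals for 4-atom specs) in every model of an ensemble. Atoms missing
#' from a model (e.g. disordered loops) yield NA in that cell; a variable
#' resolvable in no model at all raises an error.
#'
#' @param models List of [structure_model()] objects.
#' @param atom_spec Named list; each element a list of 2 or 4 atom selectors,
#'   each selector `c(chain, resno, atom_name)`.
#' @return Data frame with one row per model (`model_id` column) and one
#'   column per variable; attribute `"units"` maps variables to "A" or "deg".
#' @export
ensemble_variable_table <- function(models, atom_spec) {
  if (!length(models) || !all(vapply(models, inherits, logical(1), "structure_model")))
    stop("models must be a list of structure_model objects")
  if (!length(atom_spec) || is.null(names(atom_spec)))
    stop("atom_spec must be a named list")
  units <- character(length(atom_spec)); names(units) <- names(atom_spec)
  out <- data.frame(model_id = vapply(models, `[[`, character(1), "model_id"),
                    stringsAsFactors = FALSE)
  for (v in names(atom_spec)) {
    sel <- atom_spec[[v]]
    if (!length(sel) %in% c(2, 4))
      stop("variable '", v, "': need 2 (distance) or 4 (dihedral) atom selectors")
    units[v] <- if (length(sel) == 2) "A" else "deg"
    out[[v]] <- vapply(models, function(m) {
      xyz <- lapply(sel, function(s)
        .atom_xyz(m, s[[1]], as.numeric(s[[2]]), s[[3]]))
      if (any(vapply(xyz, is.null, logical(1)))) return(NA_real_)
      if (length(xyz) == 2) atom_distance(xyz[[1]], xyz[[2]])
      else dihedral_angle(xyz[[1]], xyz[[2]], xyz[[3]], xyz[[4]])
    }, numeric(1))
  }
  if (all(vapply(names(atom_spec), function(v) all(is.na(out[[v]])), logical(1))))
    stop("no atom spec resolvable in any model")
  attr(out, "units") <- units
  out
}
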