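## Readers and writers for the interchange formats: PDB structures (via
## bio3d), OpenDX scalar grids, per-window sample tables, derivative-profile
## and torsion-scan tables, combination-scheme YAML, and JSON result reports.

#' Read a structure model from a PDB file
#'
#' Parses ATOM and HETATM records with bio3d. Alternate locations are
#' resolved by keeping the highest-occupancy entry per (chain, resno, atom);
#' HETATM records are kept (cofactors are heteroatoms).
#'
#' @param path PDB file path.
#' @param model_id Label (defaults to the file name).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  df <- data.frame(atom = trimws(a$elety), resname = trimws(a$resid),
                   resno = a$resno, chain = a$chain,
                   x = a$x, y = a$y, z = a$z,
                   occupancy = ifelse(is.na(a$o), 1, a$o),
                   stringsAsFactors = FALSE)
  df$chain[is.na(df$chain)] <- "A"
  # altloc: keep the highest-occupancy copy of each atom
  key <- paste(df$chain, df$resno, df$atom)
  df <- df[order(key, -df$occupancy), ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$atom)), ]
  structure_model(df, model_id = model_id)
}

#' Write a structure model to a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   o = a$occupancy, b = rep(0, nrow(a)))
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Parses the "object 1 class gridpositions counts ..." dialect written by
#' common molecular-visualization tools, with values in x-fastest-last order
#' (z varies fastest).
#'
#' @param path DX file path.
#' @return A [potential_grid()].
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  num <- function(rx, line) as.numeric(strsplit(trimws(sub(rx, "", line)), "\\s+")[[1]])
  hl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(hl)) stop("not an OpenDX gridpositions file: ", path)
  dims <- as.integer(num(".*counts", hl))
  origin <- num("^\\s*origin", grep("^\\s*origin", lines, value = TRUE)[1])
  deltas <- t(vapply(grep("^\\s*delta", lines, value = TRUE)[1:3],
                     function(l) num("^\\s*delta", l), numeric(3)))
  spacing <- diag(deltas)
  istart <- grep("data follows", lines)[1] + 1
  iend <- istart - 1 + ceiling(prod(dims) / 3)
  vals <- as.numeric(unlist(strsplit(trimws(lines[istart:iend]), "\\s+")))
  if (length(vals) != prod(dims))
    stop(sprintf("expected %d values, found %d (line %d onward)",
                 prod(dims), length(vals), istart))
  # DX order: z fastest; internal array order: x fastest
  arr <- aperm(array(vals, rev(dims)), 3:1)
  potential_grid(arr, origin = origin, spacing = spacing)
}

#' Write a potential grid as OpenDX
#'
#' @param grid A [potential_grid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.6g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.6g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, 3:1))   # z fastest
  pad <- (3 - length(vals) %% 3) %% 3
  m <- matrix(c(vals, rep(NA, pad)), ncol = 3, byrow = TRUE)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.9g", r[!is.na(r)]), collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read per-window FEP sample tables
#'
#' Long-format table with mandatory header and columns `run_id`,
#' `direction`, `lambda`, `duration_ns`, `kind` (one of du_forward,
#' du_backward, du_plus, du_minus) and `value_kcal_mol`; one row per sample.
#'
#' @param path TSV/CSV file path (delimiter auto-detected from the header).
#' @param temperature_K Temperature assigned to the runs, K.
#' @return Named list of [fep_run()] objects.
#' @export
read_fep_samples <- function(path, temperature_K = 295) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  req <- c("run_id", "direction", "lambda", "duration_ns", "kind", "value_kcal_mol")
  if (!all(req %in% names(df)))
    stop("sample table must have columns: ", paste(req, collapse = ", "))
  bad <- !df$kind %in% c("du_forward", "du_backward", "du_plus", "du_minus")
  if (any(bad)) {
    warning(sum(bad), " rows with unknown sample kind skipped (first at data line ",
            which(bad)[1], ")")
    df <- df[!bad, ]
  }
  runs <- lapply(split(df, df$run_id), function(rd) {
    wins <- lapply(split(rd, rd$lambda), function(wd) {
      dur <- unique(wd$duration_ns)
      if (length(dur) != 1)
        stop("inconsistent duration_ns within a window of run ", rd$run_id[1])
      kinds <- split(wd$value_kcal_mol, wd$kind)
      lambda_window(unique(wd$lambda), duration_ns = dur,
                    du_forward = kinds$du_forward,
                    du_backward = kinds$du_backward,
                    du_plus = kinds$du_plus, du_minus = kinds$du_minus)
    })
    fep_run(rd$run_id[1], unname(wins),
            direction = match.arg(rd$direction[1],
                                  c("forward", "backward", "partial")),
            temperature_K = temperature_K)
  })
  runs
}

#' Write FEP runs as a per-window sample table
#'
#' @param runs A [fep_run()] or named list of them.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_fep_samples <- function(runs, path) {
  if (inherits(runs, "fep_run")) runs <- list(runs)
  rows <- list()
  for (run in runs) {
    stopifnot(inherits(run, "fep_run"))
    for (w in run$windows) {
      for (kind in c("du_forward", "du_backward", "du_plus", "du_minus")) {
        v <- w[[kind]]
        if (length(v))
          rows[[length(rows) + 1]] <- data.frame(
            run_id = run$run_id, direction = run$direction,
            lambda = w$lambda_value, duration_ns = w$duration_ns,
            kind = kind, value_kcal_mol = v)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write derivative-profile tables
#'
#' TSV with columns `lambda`, `dG_dlambda` and optional `weight_ns`.
#'
#' @param path File path.
#' @return [read_derivative_profile()]: a [derivative_profile()].
#' @export
read_derivative_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  derivative_profile(df$lambda, df$dG_dlambda, weights = df$weight_ns)
}

#' @param profile A [derivative_profile()].
#' @rdname read_derivative_profile
#' @export
write_derivative_profile <- function(profile, path) {
  stopifnot(inherits(profile, "derivative_profile"))
  df <- data.frame(lambda = profile$lambdas, dG_dlambda = profile$derivatives)
  if (!is.null(profile$weights)) df$weight_ns <- profile$weights
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write torsion scan tables
#'
#' Two-column TSV: `angle_deg`, `energy_kcal_mol`.
#'
#' @param path File path.
#' @return [read_scan()]: a [torsion_scan()].
#' @export
read_scan <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  torsion_scan(df$angle_deg, df$energy_kcal_mol)
}

#' @param scan A [torsion_scan()].
#' @rdname read_scan
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "torsion_scan"))
  utils::write.table(data.frame(angle_deg = scan$angles,
                                energy_kcal_mol = scan$energies),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write run-combination schemes (YAML)
#'
#' Layout: a map from lambda to a list of (run_id, weight_ns) pairs.
#'
#' @param path File path.
#' @return [read_scheme()]: a [combination_scheme()].
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  combination_scheme(lapply(y, function(members)
    data.frame(run_id = vapply(members, function(m) as.character(m[[1]]), character(1)),
               weight_ns = vapply(members, function(m) as.numeric(m[[2]]), numeric(1)))))
}

#' @param scheme A [combination_scheme()].
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "combination_scheme"))
  y <- lapply(scheme, function(m)
    lapply(seq_len(nrow(m)), function(i) list(m$run_id[i], m$weight_ns[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

## stable digest of any R object (md5 of its serialization)
.digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Write free-energy results as a JSON report
#'
#' One record per estimate: method, value, stderr, n_samples and a digest of
#' the inputs for reproducibility tracking. Units are kcal/mol throughout.
#'
#' @param results Named list of [free_energy_estimate()] objects (or plain
#'   numbers).
#' @param path Output JSON path.
#' @param inputs Optional object whose digest is recorded with each record.
#' @return Invisibly, the report list.
#' @export
write_report <- function(results, path, inputs = NULL) {
  digest <- if (is.null(inputs)) NA_character_ else .digest(inputs)
  recs <- lapply(results, function(r) {
    if (inherits(r, "free_energy_estimate"))
      list(method = r$method, value_kcal_mol = r$value,
           stderr_kcal_mol = r$stderr, n_samples = r$n_samples,
           inputs_digest = digest)
    else list(method = "value", value_kcal_mol = r, stderr_kcal_mol = NA,
              n_samples = NA, inputs_digest = digest)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(recs)
}
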