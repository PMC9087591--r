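## Combining derivative profiles across runs and quantifying hysteresis.
##
## Ionic transformations sample slowly: different runs can get trapped in
## different active-site conformations (e.g. with the Tyr-phosphate contact
## formed or broken), so the per-lambda consensus derivative is taken over a
## user-chosen subset of runs at each lambda, weighted by sampling length.

#' Weighted mean of derivative values
#'
#' \eqn{\sum w_i v_i / \sum w_i}, the per-lambda consensus derivative with
#' sampling-length weights.
#'
#' @param values Derivative values, kcal/mol.
#' @param weights Positive weights (effective sampling length, ns).
#' @return The weighted mean, kcal/mol.
#' @export
weighted_mean_derivative <- function(values, weights = rep(1, length(values))) {
  if (!length(values)) stop("empty value list")
  if (length(values) != length(weights)) stop("values and weights differ in length")
  if (any(weights <= 0)) stop("weights must be positive")
  sum(weights * values) / sum(weights)
}

#' Define a per-lambda run-combination scheme
#'
#' Maps each lambda value to the set of runs whose derivative is averaged
#' there, with a weight per run (the window sampling length in ns). Runs
#' that cover only part of the lambda range simply appear only at the
#' lambdas they sampled.
#'
#' @param members Named list: names are lambda values, each element a
#'   data.frame (or 2-column structure) with columns `run_id` and `weight_ns`.
#' @return An object of class `combination_scheme`.
#' @seealso [deprotonation_scheme()] for the scheme shipped for the
#'   MGL-PLP phosphate deprotonation runs.
#' @export
combination_scheme <- function(members) {
  if (!length(members) || is.null(names(members)))
    stop("members must be a named list keyed by lambda")
  lam <- as.numeric(names(members))
  if (any(is.na(lam))) stop("member names must be numeric lambda values")
  members <- lapply(members, function(m) {
    m <- as.data.frame(m)
    names(m) <- c("run_id", "weight_ns")
    m$run_id <- as.character(m$run_id)
    m$weight_ns <- as.numeric(m$weight_ns)
    if (!nrow(m)) stop("empty member set")
    if (any(m$weight_ns <= 0)) stop("weights must be positive")
    m
  })
  structure(members[order(lam)], class = "combination_scheme")
}

#' Run-combination scheme for the phosphate-deprotonation runs
#'
#' The shipped consensus scheme for the reference deprotonation study of the
#' MGL-PLP complex: near the protonated endpoint (lambda 0 and 0.25) runs
#' A/B/B'/C/C' are representative; at the midpoint B/B'/C/C'/d/d'; for
#' lambda >= 0.75 runs A/A'/d/d'. Full runs carry 40 ns windows and the
#' half-range runs d/d' 80 ns windows; weights are these sampling lengths.
#'
#' @return A [combination_scheme()].
#' @export
deprotonation_scheme <- function() {
  m40 <- function(ids) data.frame(run_id = ids, weight_ns = 40)
  combination_scheme(list(
    "0"    = m40(c("A", "B", "B'", "C", "C'")),
    "0.25" = m40(c("A", "B", "B'", "C", "C'")),
    "0.5"  = data.frame(run_id = c("B", "B'", "C", "C'", "d", "d'"),
                        weight_ns = c(40, 40, 40, 40, 80, 80)),
    "0.75" = data.frame(run_id = c("A", "A'", "d", "d'"),
                        weight_ns = c(40, 40, 80, 80)),
    "1"    = data.frame(run_id = c("A", "A'", "d", "d'"),
                        weight_ns = c(40, 40, 80, 80))))
}

#' Combine derivative profiles from several runs
#'
#' Assembles a consensus [derivative_profile()] by taking, at each lambda of
#' the scheme, the weighted mean over the member runs' derivatives.
#'
#' @param profiles Named list of [derivative_profile()] objects, keyed by
#'   run id.
#' @param scheme A [combination_scheme()] covering every output lambda.
#' @param lambda_tol Tolerance for matching lambda values between scheme and
#'   profiles.
#' @return A [derivative_profile()] whose weights are the summed member
#'   weights.
#' @export
combine_profiles <- function(profiles, scheme, lambda_tol = 1e-9) {
  stopifnot(inherits(scheme, "combination_scheme"))
  if (is.null(names(profiles))) stop("profiles must be a named list keyed by run id")
  lam <- as.numeric(names(scheme))
  der <- wts <- numeric(length(lam))
  for (i in seq_along(lam)) {
    mem <- scheme[[i]]
    if (!nrow(mem)) stop(sprintf("empty member set at lambda = %g", lam[i]))
    vals <- vapply(seq_len(nrow(mem)), function(j) {
      id <- mem$run_id[j]
      pr <- profiles[[id]]
      if (is.null(pr))
        stop(sprintf("run '%s' (needed at lambda = %g) not among the profiles",
                     id, lam[i]))
      k <- which(abs(pr$lambdas - lam[i]) <= lambda_tol)
      if (length(k) != 1)
        stop(sprintf("run '%s' supplies no derivative at lambda = %g", id, lam[i]))
      pr$derivatives[k]
    }, numeric(1))
    der[i] <- weighted_mean_derivative(vals, mem$weight_ns)
    wts[i] <- sum(mem$weight_ns)
  }
  derivative_profile(lam, der, weights = wts)
}

#' Forward/backward hysteresis of a free-energy estimate
#'
#' The absolute difference between the totals of a forward and a backward
#' run over the same transformation. A large gap diagnoses insufficient
#' conformational sampling.
#'
#' @param forward_total,backward_total Total Delta G of the two runs, kcal/mol.
#' @param threshold Gap above which sampling is flagged as insufficient
#'   (default 2 kcal/mol).
#' @return A list with `gap` (kcal/mol) and logical `insufficient_sampling`.
#' @examples
#' hysteresis(-79.1, -87.0)   # gap 7.9, flagged
#' hysteresis(-80.4, -80.5)   # gap 0.1, adequate
#' @export
hysteresis <- function(forward_total, backward_total, threshold = 2) {
  gap <- abs(forward_total - backward_total)
  list(gap = gap, insufficient_sampling = gap > threshold,
       threshold = threshold)
}
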