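# Temperature at which kT = 1 kcal/mol (beta = 1 units)
T_beta1 <- 1 / 0.0019872041

# independent least-squares solve via the normal equations
normal_eq_fit <- function(X, y) solve(crossprod(X), crossprod(X, y))

# random rigid motion: proper rotation (det +1) plus translation
random_rigid_motion <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

# probability masses of a wrapped-normal mixture on given bin centers
wrapped_normal_masses <- function(centers, mu, sd, w) {
  k <- -3:3
  m <- 0
  for (i in seq_along(mu)) {
    m <- m + w[i] * rowSums(sapply(k, function(kk) dnorm(centers + 360 * kk, mu[i], sd[i])))
  }
  m / sum(m)
}
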