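test_that("BAR solves the symmetric constant-sample case exactly", {
  est <- bar_estimate(rep(2, 50), rep(-2, 50))
  expect_s3_class(est, "free_energy_estimate")
  expect_equal(est$value, 2.0, tolerance = 1e-10)
  expect_identical(est$method, "BAR")

  # result independent of temperature for the symmetric case
  est2 <- bar_estimate(rep(2, 50), rep(-2, 50), temperature_K = 400)
  expect_equal(est2$value, 2.0, tolerance = 1e-10)
})

test_that("BAR is antisymmetric under exchanging the sample-set roles", {
  # reversing the transformation makes the backward samples the forward ones
  # and vice versa, and must negate the estimate exactly
  set.seed(101)
  for (rep in 1:5) {
    wf <- rnorm(400, 3, 2)
    wr <- rnorm(300, -1, 2)   # unequal sizes exercise the log(nf/nr) term
    a <- bar_estimate(wf, wr, temperature_K = T_beta1)$value
    b <- bar_estimate(wr, wf, temperature_K = T_beta1)$value
    expect_equal(a, -b, tolerance = 1e-10)
  }
})

test_that("BAR rejects empty and non-finite input", {
  expect_error(bar_estimate(numeric(0), rnorm(10)), "overlap")
  expect_error(bar_estimate(rnorm(10), numeric(0)), "overlap")
  expect_error(bar_estimate(c(1, NA), rnorm(10)), "non-finite")
  expect_error(bar_estimate(rnorm(10), c(1, Inf)), "non-finite")
})

test_that("BAR recovers the ground truth of Crooks-Gaussian work samples", {
  # forward/backward Gaussians built to satisfy the Crooks relation with
  # dG = 3, sigma^2 = 4 in beta = 1 units
  cg <- gen_crooks_gaussian(3, 2, 5e4, temperature_K = T_beta1, seed = 7)
  est <- bar_estimate(cg$du_forward, cg$du_backward, temperature_K = T_beta1)
  expect_lt(abs(est$value - 3.0), 0.05)
  expect_gt(est$stderr, 0)
  expect_lt(abs(est$value - 3.0), 3 * est$stderr)
})

test_that("finite-difference TI derivative handles constant samples exactly", {
  d <- 0.01
  w <- lambda_window(0.5, du_plus = rep(5 * d, 20), du_minus = rep(-5 * d, 20))
  expect_equal(as.numeric(fd_ti_derivative(w, d)), 5, tolerance = 1e-12)

  # delta-invariance for a constant integrand
  d2 <- d / 2
  w2 <- lambda_window(0.5, du_plus = rep(5 * d2, 20), du_minus = rep(-5 * d2, 20))
  expect_equal(as.numeric(fd_ti_derivative(w2, d2)),
               as.numeric(fd_ti_derivative(w, d)), tolerance = 1e-12)
})

test_that("one-sided TI derivative matches the Gaussian cumulant closed form", {
  # du_plus ~ N(m delta, s^2 delta^2) at kT = 1:
  # exponential averaging gives dG+ = m delta - s^2 delta^2 / 2,
  # so the one-sided derivative tends to m - s^2 delta / 2
  set.seed(22)
  m <- 40; s <- 30; d <- 0.01; n <- 2e5
  w0 <- lambda_window(0, du_plus = rnorm(n, m * d, s * d))
  est <- as.numeric(fd_ti_derivative(w0, d, temperature_K = T_beta1))
  expect_lt(abs(est - (m - s^2 * d / 2)), 5 * s / sqrt(n))

  # central difference cancels the second-cumulant term: derivative -> m
  wc <- lambda_window(0.5, du_plus = rnorm(n, m * d, s * d),
                      du_minus = rnorm(n, -m * d, s * d))
  estc <- as.numeric(fd_ti_derivative(wc, d, temperature_K = T_beta1))
  expect_lt(abs(estc - m), 5 * s / sqrt(n))
})

test_that("missing one-sided samples at an interior lambda degrade with a warning", {
  w <- lambda_window(0.5, du_plus = rep(0.01, 10))
  expect_warning(fd_ti_derivative(w, 0.01), "one-sided")
  w0 <- lambda_window(0, du_plus = rep(0.01, 10))
  expect_silent(fd_ti_derivative(w0, 0.01))   # endpoint: one-sided is expected
})

test_that("not-a-knot spline integration reproduces the reference TI totals", {
  ref <- deprotonation_reference()
  # frozen cross-check values from an independent not-a-knot implementation
  frozen <- c(solution = -80.391667, A = -79.441667, "A'" = -87.041667,
              B = -74.575, "B'" = -75.108333, C = -70.475, "C'" = -74.666667)
  for (id in names(frozen)) {
    est <- spline_integrate(ref$profiles[[id]])
    expect_equal(est$value, unname(frozen[id]), tolerance = 1e-6)
  }
  # published totals to within their printed precision
  ti_tot <- subset(ref$totals, method == "TI" & run_id %in% names(frozen))
  for (i in seq_len(nrow(ti_tot))) {
    est <- spline_integrate(ref$profiles[[ti_tot$run_id[i]]])
    expect_lt(abs(est$value - ti_tot$total_kcal_mol[i]), 0.1)
  }
})

test_that("spline integration is exact for constants and cubics and is linear", {
  grid <- seq(0, 1, 0.25)
  expect_equal(spline_integrate(derivative_profile(grid, rep(-10, 5)))$value,
               -10, tolerance = 1e-12)
  expect_equal(spline_integrate(derivative_profile(grid, 12 * grid^2))$value,
               4, tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    x <- sort(c(0, runif(4, 0.05, 0.95), 1))
    cf <- rnorm(4)
    y <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
    exact <- cf[1] + cf[2] / 2 + cf[3] / 3 + cf[4] / 4
    expect_equal(spline_integrate(derivative_profile(x, y))$value, exact,
                 tolerance = 1e-10)
    # linearity in the ordinates
    y2 <- rnorm(length(x))
    lhs <- spline_integrate(derivative_profile(x, 2 * y + 3 * y2))$value
    rhs <- 2 * spline_integrate(derivative_profile(x, y))$value +
           3 * spline_integrate(derivative_profile(x, y2))$value
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("spline integration guards its preconditions", {
  expect_error(derivative_profile(c(0, 0.5, 0.5, 1), c(1, 2, 3, 4)),
               "strictly increasing")
  two <- derivative_profile(c(0, 1), c(-33.8, -56.0))
  expect_warning(est <- spline_integrate(two), "trapezoid")
  expect_equal(est$value, -44.9, tolerance = 1e-12)
})

test_that("trapezoid and Simpson quadratures give the published cross-checks", {
  # endpoint means of the keto/enol derivative replicates
  two <- derivative_profile(c(0, 1), c(-33.8, -56.0))
  expect_equal(trapezoid_integrate(two)$value, -44.9, tolerance = 1e-12)

  ref <- deprotonation_reference()
  expect_equal(simpson_integrate(ref$profiles$solution)$value, -80.391667,
               tolerance = 1e-5)

  expect_error(simpson_integrate(derivative_profile(c(0, 0.5, 0.6, 1),
                                                    rep(1, 4))),
               "odd number")
  expect_error(simpson_integrate(derivative_profile(c(0, 0.1, 0.5, 0.7, 1),
                                                    rep(1, 5))),
               "equally spaced")

  # all three rules agree on a constant profile
  const <- derivative_profile(seq(0, 1, 0.25), rep(-7, 5))
  expect_equal(spline_integrate(const)$value, -7, tolerance = 1e-12)
  expect_equal(trapezoid_integrate(const)$value, -7, tolerance = 1e-12)
  expect_equal(simpson_integrate(const)$value, -7, tolerance = 1e-12)
})

test_that("window sums aggregate per-interval BAR contributions", {
  ref <- deprotonation_reference()
  sol <- subset(ref$bar, run_id == "solution")
  expect_equal(sum_windows(sol$dG_kcal_mol)$value, -80.5, tolerance = 1e-12)
  runA <- subset(ref$bar, run_id == "A")
  # hand sum of the printed windows (the published total -79.1 reflects
  # unrounded inputs)
  expect_equal(sum_windows(runA$dG_kcal_mol)$value, -79.2, tolerance = 1e-12)
  expect_equal(sum_windows(-3.2)$value, -3.2)
  expect_error(sum_windows(numeric(0)), "empty")
})

test_that("run-level BAR matches per-pair BAR estimates", {
  run <- gen_harmonic_alchemy(1, 4, n_frames = 2000, seed = 3)
  tot <- bar_run_total(run)
  wins <- attr(tot, "windows")
  expect_length(wins, 4)
  manual <- sum(vapply(seq_len(4), function(i)
    bar_estimate(run$windows[[i]]$du_forward,
                 run$windows[[i + 1]]$du_backward,
                 run$temperature_K)$value, numeric(1)))
  expect_equal(tot$value, manual, tolerance = 1e-12)
})
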