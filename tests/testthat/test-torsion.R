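test_that("torsion energies follow the cosine-series form", {
  ts <- torsion_series(3, 2)
  expect_equal(torsion_energy(ts, 60), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(ts, 0), 4, tolerance = 1e-12)

  set.seed(4)
  chi <- runif(20, -720, 720)
  expect_equal(torsion_energy(ts, chi), torsion_energy(ts, chi + 360),
               tolerance = 1e-9)

  # linearity: a two-term series equals the sum of its single-term parts
  t1 <- torsion_series(1, 0.7, 30)
  t2 <- torsion_series(2, 1.1, -45)
  t12 <- torsion_series(c(1, 2), c(0.7, 1.1), c(30, -45))
  expect_equal(torsion_energy(t12, chi),
               torsion_energy(t1, chi) + torsion_energy(t2, chi),
               tolerance = 1e-12)
})

test_that("angles wrap into [-180, 180) with 180 -> -180", {
  expect_equal(wrap_angle(-210), 150)
  expect_equal(wrap_angle(180), -180)
  expect_equal(wrap_angle(37), 37)
  set.seed(6)
  x <- runif(50, -1000, 1000)
  expect_equal(wrap_angle(wrap_angle(x)), wrap_angle(x))
  expect_true(all(wrap_angle(x) >= -180 & wrap_angle(x) < 180))
})

test_that("cosine-series fitting recovers in-class scans exactly", {
  ang <- seq(-180, 180, length.out = 14)[-14]
  truth <- torsion_series(2, 1.5, 0)
  fit <- fit_cosine_series(torsion_scan(ang, torsion_energy(truth, ang)),
                           periodicities = 2)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-10)
  expect_equal(fit$series$terms$K, 1.5, tolerance = 1e-10)
  expect_equal(fit$series$terms$delta, 0, tolerance = 1e-8)

  # a constant added to the scan is absorbed by the offset
  fit2 <- fit_cosine_series(torsion_scan(ang, torsion_energy(truth, ang) + 5),
                            periodicities = 2)
  expect_equal(fit2$series$terms$K, fit$series$terms$K, tolerance = 1e-10)
  expect_equal(fit2$series$terms$delta, fit$series$terms$delta, tolerance = 1e-8)

  expect_error(fit_cosine_series(torsion_scan(ang[1:5], rep(1, 5)),
                                 periodicities = 1:3),
               "underdetermined")
})

test_that("noisy-scan fits agree with a normal-equations oracle", {
  set.seed(8)
  ang <- seq(-180, 170, by = 10)
  truth <- torsion_series(c(1, 3), c(0.9, 2.1), c(20, -60))
  e <- torsion_energy(truth, ang) + rnorm(length(ang), 0, 0.1)
  scan <- torsion_scan(ang, e)
  fit <- fit_cosine_series(scan, periodicities = c(1, 3))

  X <- cbind(1, cos(scan$angles * pi / 180), sin(scan$angles * pi / 180),
             cos(3 * scan$angles * pi / 180), sin(3 * scan$angles * pi / 180))
  cf <- normal_eq_fit(X, scan$energies)
  K_or <- c(sqrt(cf[2]^2 + cf[3]^2), sqrt(cf[4]^2 + cf[5]^2))
  d_or <- atan2(c(cf[3], cf[5]), c(cf[2], cf[4])) * 180 / pi
  expect_equal(fit$series$terms$K, K_or, tolerance = 1e-8)
  expect_equal(fit$series$terms$delta, d_or, tolerance = 1e-8)
})

test_that("Metropolis sampling is seeded-deterministic and hits a flat target", {
  flat <- torsion_series(1, 0)
  s1 <- metropolis_sample(flat, n_samples = 1e5, seed = 13, step_deg = 60)
  s2 <- metropolis_sample(flat, n_samples = 1e5, seed = 13, step_deg = 60)
  expect_identical(s1, s2)

  cnt <- angle_histogram(s1, n_bins = 18)$masses * length(s1)
  p <- chisq.test(cnt)$p.value
  expect_gt(p, 0.01)
})

test_that("Metropolis samples follow the Boltzmann density of the potential", {
  ts <- torsion_series(1, 3, 0)
  s <- metropolis_sample(ts, temperature_K = 295, n_samples = 5e4,
                         seed = 17, step_deg = 40)
  h <- angle_histogram(s, n_bins = 20)
  q <- boltzmann_bin_masses(ts, h$bin_edges, 295)
  n <- length(s)
  # binwise agreement within 5 sigma of the multinomial error (correlated
  # chain samples inflate the nominal error, hence the slack)
  sig <- sqrt(q$masses * (1 - q$masses) / n)
  expect_true(all(abs(h$masses - q$masses) < 5 * pmax(sig, 1e-4) + 0.01))
  # mode at the potential minimum (chi = 180/-180 for delta = 0)
  expect_gt(mean(abs(s) > 120), 0.8)
})

test_that("distribution matching is a fixed point on the model's own distribution", {
  ts <- torsion_series(c(1, 2), c(0.6, 1.0), c(-10, 40))
  edges <- seq(-180, 180, length.out = 21)
  target <- boltzmann_bin_masses(ts, edges, 295)
  out <- match_distribution(ts, target, iterations = 4, n_samples = 2e4, seed = 5)
  expect_gt(attr(out, "overlap"), 0.94)
  grid <- seq(-180, 179, 2)
  dv <- torsion_energy(out, grid) - torsion_energy(ts, grid)
  expect_lt(sd(dv), 0.15)   # parameters unchanged within sampling noise
})

test_that("distribution matching recovers a known potential from a zero start", {
  vstar <- torsion_series(c(1, 2), c(0.6, 1.4), c(-10, 40))
  edges <- seq(-180, 180, length.out = 21)
  target <- boltzmann_bin_masses(vstar, edges, 295)
  fit <- match_distribution(torsion_series(1:3, c(0, 0, 0)), target,
                            iterations = 15, n_samples = 2e4, seed = 42)
  grid <- seq(-180, 179, 1)
  dv <- torsion_energy(fit, grid) - torsion_energy(vstar, grid)
  rms <- sqrt(mean((dv - mean(dv))^2))   # up to an additive constant
  expect_lt(rms, 0.2)
  hist <- attr(fit, "history")
  # overlap improves over the first iterations of the refinement
  expect_gt(max(hist[1:4]) , hist[1])
  expect_gt(attr(fit, "overlap"), 0.95)
})

test_that("dihedral stanza rendering lists one line per cosine term", {
  ts <- torsion_series(c(1, 2, 3), c(0.5, 1.2, 0.3), c(0, 180, 0))
  lines <- as_dihedral_stanza(ts)
  expect_length(lines, 3)
  expect_match(lines[1], "^C4\\s+C4A\\s+NZ\\s+CE\\s+")
  expect_match(lines[2], "\\s2\\s+180")
})
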