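test_that("dihedral angles follow the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(0,0,1), c(0,0,0), c(1,0,0), c(1,0,1)), 0,
               tolerance = 1e-12)
  expect_equal(dihedral_angle(c(0,0,1), c(0,0,0), c(1,0,0), c(1,0,-1)), -180,
               tolerance = 1e-12)
  expect_equal(dihedral_angle(c(0,0,1), c(0,0,0), c(1,0,0), c(1,1,0)), -90,
               tolerance = 1e-12)
})

test_that("dihedral angles agree with bio3d on random quadruples", {
  set.seed(31)
  for (rep in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    oracle <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(wrap_angle(mine), wrap_angle(oracle), tolerance = 1e-6)
  }
})

test_that("dihedrals are rigid-motion invariant and mirror antisymmetric", {
  set.seed(32)
  for (rep in 1:10) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    rm_ <- random_rigid_motion()
    q <- sweep(p %*% t(rm_$R), 2, rm_$t, "+")
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-8)
    m <- p; m[, 3] <- -m[, 3]   # reflection
    expect_equal(wrap_angle(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])),
                 wrap_angle(-ref), tolerance = 1e-8)
  }
})

test_that("degenerate dihedral geometry raises errors", {
  expect_error(dihedral_angle(c(0,0,0), c(0,0,0), c(1,0,0), c(1,1,0)),
               "coincident")
  expect_error(dihedral_angle(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "collinear")
})

test_that("atom distances are Euclidean and symmetric", {
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(0, 1, 0)), 1.0)
  set.seed(33)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(atom_distance(a, b), sqrt(sum((a - b)^2)))
  expect_equal(atom_distance(a, b), atom_distance(b, a))
})

test_that("contact occupancy counts entries at or under the cutoff", {
  expect_equal(contact_occupancy(c(2.8, 3.0, 4.0, 3.4), 3.5), 0.75)
  expect_equal(contact_occupancy(c(4.0, 5.0), 3.5), 0)
  d63 <- c(rep(3.0, 46), rep(4.2, 17))
  expect_equal(contact_occupancy(d63, 3.5), 46 / 63, tolerance = 1e-3)
  # monotone non-increasing as the cutoff tightens; bounded in [0, 1]
  set.seed(34)
  d <- runif(40, 2, 6)
  occ <- vapply(seq(6, 2, -0.5), function(ct) contact_occupancy(d, ct), numeric(1))
  expect_true(all(diff(occ) <= 0))
  expect_true(all(occ >= 0 & occ <= 1))
  # missing entries (disordered loops) drop out of the denominator
  expect_equal(contact_occupancy(c(3, 3, NA, 4), 3.5), 2 / 3)
  expect_error(contact_occupancy(numeric(0), 3.5), "empty")
})

test_that("NZ orientation classes split on the hydrogen-bond distance", {
  expect_equal(classify_nz_orientation(2.9)$orientation, "A")
  expect_equal(classify_nz_orientation(4.5)$orientation, "B")
  expect_equal(classify_nz_orientation(3.5)$orientation, "A")  # closed interval
  res <- classify_nz_orientation(c(2.9, 4.5, 3.6), c(10, -20, 30))
  expect_equal(res$orientation, c("A", "B", "B"))
  expect_equal(res$c5_c4_c4p_nz, c(10, -20, 30))
})

test_that("chi peak assignment partitions the circle at the midpoints", {
  expect_equal(chi_peak_assignment(150), "peak1")
  expect_equal(chi_peak_assignment(-130), "peak2")
  expect_equal(chi_peak_assignment(-210), "peak1")   # wraps to +150
  # boundaries: 10 starts peak1, -170 starts peak2
  expect_equal(chi_peak_assignment(c(10, 9.99, -170, -170.01)),
               c("peak1", "peak2", "peak2", "peak1"))
  grid <- seq(-180, 179.5, 0.5)
  pk <- chi_peak_assignment(grid)
  expect_true(all(pk %in% c("peak1", "peak2")))
  expect_true(all(table(pk) > 0))
})

test_that("ensemble variable tables round-trip generated geometry", {
  models <- list(gen_toy_structure(150, c("NZ-O3" = 2.9), "m1", seed = 1),
                 gen_toy_structure(-130, c("NZ-O3" = 4.5), "m2", seed = 2))
  spec <- list(chi = list(c("A", 1, "C4"), c("A", 1, "C4A"),
                          c("A", 2, "NZ"), c("A", 2, "CE")),
               NZ_O3 = list(c("A", 2, "NZ"), c("A", 3, "O3")))
  tab <- ensemble_variable_table(models, spec)
  expect_equal(tab$chi, c(150, -130), tolerance = 1e-6)
  expect_equal(tab$NZ_O3, c(2.9, 4.5), tolerance = 1e-6)
  expect_equal(attr(tab, "units"), c(chi = "deg", NZ_O3 = "A"))

  # deleting one atom yields a missing marker in that cell only
  m3 <- models[[2]]
  m3$atoms <- m3$atoms[m3$atoms$atom != "O3", ]
  tab2 <- ensemble_variable_table(list(models[[1]], m3), spec)
  expect_true(is.na(tab2$NZ_O3[2]))
  expect_false(is.na(tab2$chi[2]))
  expect_equal(tab2$NZ_O3[1], 2.9, tolerance = 1e-6)

  # sorting by a variable matches an independent sort of the truth
  set.seed(35)
  chis <- wrap_angle(runif(6, -180, 180))
  ms <- lapply(seq_along(chis), function(i)
    gen_toy_structure(chis[i], model_id = paste0("s", i), seed = i))
  tb <- ensemble_variable_table(ms, spec["chi"])
  expect_equal(tb$model_id[order(tb$chi)], paste0("s", order(chis)))

  expect_error(ensemble_variable_table(models,
                                       list(v = list(c("Z", 9, "XX"), c("Z", 9, "YY")))),
               "resolvable")
})
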