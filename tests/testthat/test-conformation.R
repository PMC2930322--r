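test_that("end-to-end length covers dimer, hairpin and tetramer conventions", {
  expect_equal(end_to_end_length(build_dimer()), 50)
  expect_equal(end_to_end_length(hairpin_dimer()), 2)
  expect_lt(abs(end_to_end_length(build_tetramer()) - 75), 1.1)
  one <- single_bead_model()
  expect_error(end_to_end_length(one), "2 beads")
})

test_that("Kabsch RMSD satisfies its identities and matches references", {
  p <- bead_coords(build_dimer())
  expect_equal(kabsch_rmsd(p, p), 0)
  for (s in 1:4) {
    q <- random_rigid(p, s)
    expect_lt(kabsch_rmsd(p, q), 1e-9)
  }
  # symmetry and triangle inequality on random triples
  withr::with_seed(20, {
    for (i in 1:5) {
      a <- matrix(rnorm(30), 10); b <- matrix(rnorm(30), 10)
      cc <- matrix(rnorm(30), 10)
      expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
      expect_lte(kabsch_rmsd(a, cc),
                 kabsch_rmsd(a, b) + kabsch_rmsd(b, cc) + 1e-9)
    }
  })
  expect_error(kabsch_rmsd(p, p[1:10, ]), "size")
  # displaced-bead case against a random-rotation enumeration oracle
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  b <- a; b[3, ] <- b[3, ] + c(0.3, -0.2, 0.4)
  kb <- kabsch_rmsd(a, b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  best <- withr::with_seed(5, {
    min(vapply(1:20000, function(i) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
    }, numeric(1)))
  })
  expect_lte(kb, best + 1e-9)        # optimal beats every sampled rotation
  expect_lt(best - kb, 0.005)        # and the sampling approaches it
  # independent reference implementation agrees (bio3d rounds to 3 digits)
  expect_equal(kb, bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                               fit = TRUE),
               tolerance = 0.005)
})

test_that("projection area matches closed forms and is rigid-motion invariant", {
  one <- single_bead_model()
  expect_equal(projection_area(one, grid_resolution = 0.1), pi,
               tolerance = 0.02 * pi)
  d <- build_dimer()
  # straight rod: stadium footprint 50 x 2 + pi
  expect_equal(projection_area(d), 50 * 2 + pi, tolerance = 0.05 * 103)
  p <- bead_coords(d)
  for (s in 1:3) {
    q <- random_rigid(p, s + 30)
    expect_equal(projection_area(d, positions = q), projection_area(d),
                 tolerance = 0.02 * 103)
  }
  expect_error(projection_area(d, grid_resolution = 2), "radius")
  # the minimal-cross-section convention gives a much smaller area
  expect_lt(projection_area(d, plane = "first_axis"), 20)
})

test_that("coarse-grained SASA reproduces sphere identities", {
  one <- single_bead_model()
  expect_equal(cg_sasa(one), 4 * pi, tolerance = 1e-6)
  expect_equal(cg_sasa(one, probe_radius = 0.4), 4 * pi * 1.4^2,
               tolerance = 1e-6)
  far <- two_bead_model(10)
  expect_equal(cg_sasa(far), 2 * 4 * pi, tolerance = 1e-6)
  coincident <- two_bead_model(0)
  expect_equal(cg_sasa(coincident), 4 * pi, tolerance = 1e-6)
  d <- build_dimer()
  base <- cg_sasa(d)
  for (s in 1:3) {
    q <- random_rigid(bead_coords(d), s + 60)
    expect_equal(cg_sasa(d, positions = q), base, tolerance = 0.02 * base)
  }
})

test_that("WLC tangent angle is the documented function of L and Lp", {
  expect_equal(wlc_mean_tangent_angle(25, 25), acos(exp(-1)) * 180 / pi)
  expect_equal(wlc_mean_tangent_angle(25, 25), 68.4, tolerance = 0.05)
  expect_equal(wlc_mean_tangent_angle(0, 25), 0)
  expect_equal(wlc_mean_tangent_angle(1e9, 25), 90, tolerance = 1e-6)
  # strictly increasing in L, strictly decreasing in Lp
  L <- seq(1, 100, by = 1)
  expect_true(all(diff(wlc_mean_tangent_angle(L, 25)) > 0))
  Lp <- seq(5, 100, by = 1)
  expect_true(all(diff(wlc_mean_tangent_angle(25, Lp)) < 0))
})

test_that("persistence-length estimator flags rigid chains and sees floppy ones", {
  # rigid straight trajectory: correlations never decay
  m <- build_coil(20, 1)
  cfg <- sim_config(n_steps = 3000, record_every = 50,
                    environment = "solution")
  tr <- run_simulation(m, ff = forcefield_params(), config = cfg,
                       zero_temperature = TRUE)
  lp <- estimate_persistence_length(tr, segment_label = NULL,
                                    discard_frac = 0)
  expect_true(is.infinite(lp))
  expect_equal(attr(lp, "flag"), "ge_contour")
  # freely jointed chain (no bending, no excluded volume): Lp under 1.5 nm
  ffj <- forcefield_params(bend_k_coil = 0, bend_k_hinge = 0,
                           excluded_eps = 0)
  cfgj <- sim_config(n_steps = 4e5, seed = 1, environment = "solution",
                     record_every = 2000)
  trj <- run_simulation(m, ff = ffj, config = cfgj)
  lpj <- estimate_persistence_length(trj, segment_label = NULL)
  expect_lt(lpj, 1.5)
  expect_error(estimate_persistence_length(tr, max_lag = 5,
                                           discard_frac = 0.9),
               "few frames")
})

test_that("equivalent disk diameter inverts the disk area", {
  expect_equal(equivalent_disk_diameter(pi), 2)
  expect_equal(equivalent_disk_diameter(587), 27.3, tolerance = 0.05)
  expect_equal(equivalent_disk_diameter(246), 17.7, tolerance = 0.05)
  expect_equal(equivalent_disk_diameter(0), 0)
  expect_error(equivalent_disk_diameter(-1), ">= 0")
})
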