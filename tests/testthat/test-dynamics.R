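test_that("fixed seeds give bitwise-identical trajectories", {
  m <- build_coil(10, 1)
  cfg <- sim_config(n_steps = 2e4, seed = 42, environment = "solution",
                    record_every = 1000)
  t1 <- run_simulation(m, ff = forcefield_params(), config = cfg)
  t2 <- run_simulation(m, ff = forcefield_params(), config = cfg)
  expect_identical(t1$frames, t2$frames)
  cfg2 <- sim_config(n_steps = 2e4, seed = 43, environment = "solution",
                     record_every = 1000)
  t3 <- run_simulation(m, ff = forcefield_params(), config = cfg2)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("deposition pull acts only above the height threshold", {
  cfg <- sim_config(environment = "substrate")
  f <- apply_deposition_pull(rbind(c(0, 0, 6), c(0, 0, 4)), cfg)
  expect_lt(f[1, 3], 0)
  expect_equal(f[1, 3], -0.0012 * 18 * 10)   # per-residue force x 18 x nm
  expect_equal(f[2, ], c(0, 0, 0))
  # all beads below threshold: no external-pull energy
  d <- place_for_deposition(build_dimer(), 3)
  e <- total_energy(d, ff = forcefield_params(),
                    pull = list(force_per_bead = 0.216, z_threshold = 5))
  expect_equal(e$external_pull, 0)
})

test_that("environment modes modify the system as documented", {
  d <- build_dimer()
  ff <- forcefield_params()
  sol <- apply_environment_mode(d, ff, "solution")
  expect_identical(sol$model, d)
  expect_identical(sol$ff, ff)
  expect_error(apply_environment_mode(d, ff, "vacuum"), "unknown")
  # glutaraldehyde on a straight chain: no close nonbonded pairs
  glu <- apply_environment_mode(d, ff, "substrate+glutaraldehyde")
  expect_equal(nrow(glu$model$crosslinks), 0)
  # on a tight hairpin the facing arms (1.2 nm apart, inside the 1.5 nm
  # capture radius) are captured
  glu2 <- apply_environment_mode(hairpin_dimer(gap = 1.2), ff,
                                 "substrate+glutaraldehyde")
  expect_gt(nrow(glu2$model$crosslinks), 10)
  expect_true(all(glu2$model$crosslinks$b0 > 0))
  # calcium switches the attraction on
  ca <- apply_environment_mode(d, ff, "substrate+calcium")
  expect_true(isTRUE(ca$ff$ca_on))
})

test_that("calcium attraction compacts the chain relative to plain salt", {
  m <- build_dimer()
  rgs <- function(ff, seed) {
    cfg <- sim_config(n_steps = 1e6, seed = seed, environment = "solution",
                      record_every = 5000)
    tl <- tidy(run_simulation(m, ff = ff, config = cfg))
    mean(tail(tl$rg, 70))
  }
  ff_plain <- forcefield_params()
  ff_ca <- forcefield_params(ca_eps = 5)
  ff_ca$ca_on <- TRUE
  plain <- mean(c(rgs(ff_plain, 5), rgs(ff_plain, 6)))
  calcium <- mean(c(rgs(ff_ca, 5), rgs(ff_ca, 6)))
  expect_lt(calcium, plain)
})

test_that("zero-temperature dynamics never increase the energy", {
  m <- build_dimer()
  withr::with_seed(2, {
    p <- bead_coords(m) + matrix(rnorm(153, 0, 0.1), 51)
  })
  m$beads$x <- p[, 1]; m$beads$y <- p[, 2]; m$beads$z <- p[, 3]
  ff <- forcefield_params()
  cfg <- sim_config(n_steps = 5000, timestep = 1e-4, record_every = 250,
                    environment = "solution")
  tr <- run_simulation(m, ff = ff, config = cfg, zero_temperature = TRUE)
  en <- vapply(seq_len(n_frames(tr)), function(f) {
    total_energy(m, ff = ff, positions = frame_positions(tr, f))$total
  }, numeric(1))
  expect_true(all(diff(en) <= 1e-9))
  expect_lt(en[length(en)], en[1])
})

test_that("bending energy equipartitions to ~kBT per joint", {
  m <- build_coil(25, 1)
  ff <- forcefield_params()
  cfg <- sim_config(n_steps = 4e5, seed = 12, environment = "solution",
                    record_every = 2000)
  tr <- run_simulation(m, ff = ff, config = cfg)
  nf <- n_frames(tr)
  eb <- vapply(seq(nf %/% 2, nf), function(f) {
    total_energy(m, ff = ff, positions = frame_positions(tr, f))$bending
  }, numeric(1))
  # two transverse bending modes per joint -> mean energy kB T
  per_joint <- mean(eb) / nrow(m$joints)
  expect_equal(per_joint, 0.59616, tolerance = 0.15)
})

test_that("convergence check flags plateaus and drifts correctly", {
  m <- build_dimer()
  cfg <- sim_config(n_steps = 100, record_every = 10,
                    environment = "solution")
  st <- run_simulation(m, ff = forcefield_params(), config = cfg,
                       zero_temperature = TRUE)
  cv <- check_convergence(st, window = 5)
  expect_true(cv$converged)
  expect_lt(max(cv$rmsd$rmsd), 1e-2)
  # manufactured linear drift: not converged
  drift <- st
  for (f in seq_len(n_frames(drift))) {
    drift$frames[, 1, f] <- drift$frames[, 1, f] +
      2 * f * seq_len(51) / 51    # growing shear, not removable rigidly
  }
  expect_false(check_convergence(drift, window = 8)$converged)
  expect_error(check_convergence(st, window = 1e4), "window")
})

test_that("a deposited chain settles at the calibrated contact height", {
  m <- place_for_deposition(build_coil(10, 1), 3)
  lat <- ifplast:::deposition_lattice(m, margin = 10)
  cfg <- sim_config(n_steps = 4e5, seed = 3, environment = "substrate",
                    record_every = 4000)
  tr <- run_simulation(m, lat, forcefield_params(), cfg)
  tl <- tidy(tr)
  final_z <- mean(tail(tl$mean_z, 20))
  expect_gt(final_z, 0.3)
  expect_lt(final_z, 1.0)
})

test_that("adsorption traps the conformation relative to solution", {
  # frame-to-frame mobility after contact is far below the free chain's
  m <- build_coil(20, 1)
  frame_rmsd <- function(tr) {
    nf <- n_frames(tr)
    mean(vapply(seq(nf %/% 2 + 1, nf), function(f) {
      kabsch_rmsd(frame_positions(tr, f), frame_positions(tr, f - 1))
    }, numeric(1)))
  }
  cfg_sol <- sim_config(n_steps = 3e5, timestep = 1e-4, seed = 9,
                        environment = "solution", record_every = 3000)
  mob_sol <- frame_rmsd(run_simulation(m, ff = forcefield_params(),
                                       config = cfg_sol))
  md <- place_for_deposition(m, 3)
  lat <- ifplast:::deposition_lattice(md, margin = 10)
  cfg_sub <- sim_config(n_steps = 3e5, seed = 9, environment = "substrate",
                        record_every = 3000)
  mob_sub <- frame_rmsd(run_simulation(md, lat, forcefield_params(),
                                       config = cfg_sub))
  expect_lt(mob_sub, mob_sol)
})

test_that("a hopeless timestep is reported as a force overflow", {
  m <- build_dimer()
  cfg <- sim_config(n_steps = 100, timestep = 10, seed = 1,
                    environment = "solution", record_every = 10)
  expect_error(run_simulation(m, ff = forcefield_params(), config = cfg),
               "force overflow|timestep")
})

test_that("trajectory accessors and tidiers are consistent", {
  m <- build_coil(8, 1)
  cfg <- sim_config(n_steps = 1e4, seed = 2, environment = "solution",
                    record_every = 500)
  tr <- run_simulation(m, ff = forcefield_params(), config = cfg)
  expect_equal(n_frames(tr), 1e4 / 500 + 1)
  expect_equal(frame_positions(tr, 1), unname(bead_coords(m)))
  tl <- tidy(tr)
  expect_equal(nrow(tl), n_frames(tr))
  expect_true(all(tl$end_to_end <= 8 + 2 * 1 + 1e-9))  # contour + 2 radii
  g <- glance(tr)
  expect_equal(g$n_beads, 9)
  expect_equal(g$environment, "solution")
})
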