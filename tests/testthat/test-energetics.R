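test_that("Lennard-Jones pair energy has its minimum at the zero-force distance", {
  lj <- lj_params(1.48, 0.49)
  expect_equal(lj_pair_energy(0.49, lj), -1.48)
  expect_equal(lj_pair_energy(2^(-1 / 6) * 0.49, lj), 0, tolerance = 1e-12)
  expect_lt(abs(lj_pair_energy(4.9, lj)), 1e-5 * 1.48)
  # C1 continuity: numerical derivative vanishes at r_min
  h <- 1e-7
  dnum <- (lj_pair_energy(0.49 + h, lj) - lj_pair_energy(0.49 - h, lj)) / (2 * h)
  expect_lt(abs(dnum), 1e-6)
  # the well is the global minimum on a scan
  r <- seq(0.3, 2.5, by = 1e-3)
  expect_equal(r[which.min(lj_pair_energy(r, lj))], 0.49, tolerance = 2e-3)
  expect_error(lj_pair_energy(0, lj), "> 0")
})

test_that("adhesion density converts to the printed per-residue energies", {
  expect_equal(gamma_to_per_residue_energy(50, 0.28), 2.01, tolerance = 0.005)
  expect_equal(gamma_to_per_residue_energy(60, 0.28), 2.42, tolerance = 0.005)
  expect_equal(gamma_to_per_residue_energy(0, 0.28), 0)
  expect_error(gamma_to_per_residue_energy(-1, 0.28), ">= 0")
  expect_error(gamma_to_per_residue_energy(50, 0), "> 0")
})

test_that("bending constant follows Lp * kBT / b", {
  expect_equal(bending_constant_from_persistence_length(25, 1, 300), 14.90,
               tolerance = 0.01)
  expect_equal(bending_constant_from_persistence_length(0, 1, 300), 0)
  expect_equal(bending_constant_from_persistence_length(50, 1, 300),
               2 * bending_constant_from_persistence_length(25, 1, 300))
})

test_that("substrate adhesion energy is additive, cut off, and periodic", {
  lat <- build_substrate(width = 24, depth = 24, lj = lj_params(1, 0.7))
  # single bead above the cutoff contributes nothing
  expect_equal(substrate_adhesion_energy(matrix(c(0, 0, 2.6), 1), lat), 0)
  # additivity: two beads far apart laterally, same height (0.8 nm is in
  # the attractive zone above every lattice site)
  e1 <- substrate_adhesion_energy(matrix(c(-5, 0, 0.8), 1), lat)
  e2 <- substrate_adhesion_energy(matrix(c(5, 0, 0.8), 1), lat)
  e12 <- substrate_adhesion_energy(rbind(c(-5, 0, 0.8), c(5, 0, 0.8)), lat)
  expect_lt(e1, 0)
  expect_equal(e12, e1 + e2, tolerance = 1e-12)
  # translation by one lattice vector leaves the energy unchanged (away
  # from the lattice edges)
  for (z in c(0.45, 0.8, 1.5)) {
    probe <- matrix(c(0.31, 0.17, z), 1)
    ea <- substrate_adhesion_energy(probe, lat)
    eb <- substrate_adhesion_energy(probe + c(0.98, 0, 0), lat)
    ec <- substrate_adhesion_energy(probe + c(0.49, 0.98 * sqrt(3) / 2, 0), lat)
    expect_equal(ea, eb, tolerance = 1e-9)
    expect_equal(ea, ec, tolerance = 1e-9)
  }
  expect_error(substrate_adhesion_energy(matrix(c(40, 0, 0.5), 1), lat),
               "extent")
})

test_that("well-depth calibration is exact and linear in the target", {
  lat <- build_substrate(width = 20, depth = 20)
  # degenerate lattice of a single bead: epsilon equals the target
  lat1 <- lat
  lat1$positions <- lat1$positions[which.min(abs(lat1$positions$x) +
                                               abs(lat1$positions$y)), ]
  eps1 <- calibrate_bead_well_depth(3.7, 0.7, lat1)
  expect_equal(as.numeric(eps1), 3.7, tolerance = 1e-6)
  # linear scaling on the full lattice
  ea <- as.numeric(calibrate_bead_well_depth(10, 0.7, lat))
  eb <- as.numeric(calibrate_bead_well_depth(20, 0.7, lat))
  expect_equal(eb, 2 * ea, tolerance = 1e-12)
  # round trip against the brute-force z-scan for 5 random targets
  withr::with_seed(4, {
    for (target in runif(5, 5, 40)) {
      eps <- calibrate_bead_well_depth(target, 0.7, lat)
      cal <- lat
      cal$lj <- lj_params(as.numeric(eps), 0.7)
      probe_xy <- ifplast:::hollow_site(cal)
      scan <- vapply(seq(0.2, 2.5, by = 1e-3), function(z) {
        substrate_adhesion_energy(matrix(c(probe_xy, z), 1), cal)
      }, numeric(1))
      expect_equal(min(scan), -target, tolerance = 1e-6 * target)
    }
  })
  expect_error(calibrate_bead_well_depth(-1, 0.7, lat), "> 0")
  # lateral corrugation: the well over a three-fold hollow is markedly
  # deeper than over a lattice bead, so adsorbed beads are pinned
  cal <- lat
  cal$lj <- lj_params(as.numeric(calibrate_bead_well_depth(26.64, 0.7, lat)),
                      0.7)
  well_at <- function(xy) {
    optimize(function(z) {
      substrate_adhesion_energy(matrix(c(xy, z), 1), cal)
    }, c(0.2, 2.5))$objective
  }
  lp <- as.matrix(cal$positions)
  atop <- lp[which.min(rowSums(lp[, 1:2]^2)), 1:2]
  hollow <- ifplast:::hollow_site(cal)
  expect_lt(well_at(hollow), -26.6)
  expect_lt(well_at(atop), 0)
  expect_gt(well_at(atop) - well_at(hollow), 10)  # barrier >> kBT
})

test_that("energy breakdown sums exactly and matches closed forms", {
  d <- build_dimer()
  ff <- forcefield_params()
  e0 <- total_energy(d, ff = ff)
  expect_equal(e0$bending, 0)
  expect_equal(e0$bonded, 0)
  expect_equal(e0$adhesion, 0)
  # one 90-degree joint: U = 0.5 k (pi/2)^2
  m3 <- right_angle_chain()
  ff3 <- forcefield_params(excluded_eps = 0)
  e3 <- total_energy(m3, ff = ff3)
  expect_equal(e3$bending, 0.5 * ff3$bend_k_coil * (pi / 2)^2,
               tolerance = 1e-12)
  # bookkeeping identity on random configurations
  withr::with_seed(8, {
    for (i in 1:5) {
      p <- bead_coords(d) + matrix(rnorm(153, 0, 0.2), 51)
      e <- total_energy(d, ff = ff, positions = p)
      expect_lt(abs(e$total - (e$bonded + e$bending + e$excluded +
                                 e$electrostatic + e$adhesion +
                                 e$external_pull)), 1e-9)
    }
  })
  # electrostatics vanish at zero bead charge
  d0 <- build_dimer(coil_charge = 0)
  pb <- bead_coords(d0) + matrix(0.05, 51, 3) * seq_len(51)
  expect_equal(total_energy(d0, ff = ff, positions = pb)$electrostatic, 0)
})

test_that("integrator forces equal the energy gradient", {
  withr::with_seed(7, {
    m <- build_tetramer()
    p <- bead_coords(m) + matrix(rnorm(306, 0, 0.15), 102)
    m$beads$x <- p[, 1]; m$beads$y <- p[, 2]; m$beads$z <- p[, 3]
    ff <- forcefield_params()
    en <- function(pos) total_energy(m, NULL, ff, positions = pos)$total
    cfg <- sim_config(n_steps = 1, timestep = 1e-9, record_every = 1,
                      environment = "solution", seed = 1)
    tr <- run_simulation(m, ff = ff, config = cfg, zero_temperature = TRUE)
    Fc <- (frame_positions(tr, 2) - frame_positions(tr, 1)) / 1e-9
    h <- 1e-6
    for (i in sample(102, 6)) {
      for (k in 1:3) {
        pp <- p; pp[i, k] <- pp[i, k] + h
        pm <- p; pm[i, k] <- pm[i, k] - h
        g <- (en(pp) - en(pm)) / (2 * h)
        expect_equal(Fc[i, k], -g, tolerance = 1e-3)
      }
    }
  })
})

test_that("tabulated substrate force tracks the exact lattice-sum gradient", {
  m <- build_coil(6, 1)
  m <- place_for_deposition(m, 0.6)
  withr::with_seed(3, m$beads$z <- m$beads$z + runif(7, -0.1, 0.4))
  lat <- ifplast:::deposition_lattice(m, margin = 8)
  p <- bead_coords(m)
  en <- function(pos) substrate_adhesion_energy(pos, lat, 2.5)
  ffz <- forcefield_params(bond_k = 0, bend_k_coil = 0, bend_k_hinge = 0,
                           excluded_eps = 0)
  ffz$coulomb_prefactor <- 0
  cfg <- sim_config(n_steps = 1, timestep = 1e-12, record_every = 1,
                    environment = "substrate", seed = 1)
  tr <- run_simulation(m, lat, ffz, cfg, zero_temperature = TRUE,
                       check_start = FALSE)
  Fc <- (frame_positions(tr, 2) - frame_positions(tr, 1)) / 1e-12
  h <- 1e-6
  g <- matrix(0, nrow(p), 3)
  for (i in seq_len(nrow(p))) {
    for (k in 1:3) {
      pp <- p; pp[i, k] <- pp[i, k] + h
      pm <- p; pm[i, k] <- pm[i, k] - h
      g[i, k] <- (en(pp) - en(pm)) / (2 * h)
    }
  }
  expect_lt(max(abs(Fc + g)) / max(abs(g)), 0.05)
})
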