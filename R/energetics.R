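# Energy model: substrate Lennard-Jones adhesion with its calibration, and
# the coarse-grained chain force field (bonds, bending, excluded volume,
# screened electrostatics). Units: nm, kcal/mol, elementary charges.

#' Lennard-Jones parameters
#'
#' @param well_depth Energy well depth epsilon (kcal/mol), stored positive.
#' @param r_min Distance of zero force sigma (nm), i.e. the location of the
#'   potential minimum.
#' @return A list of class `ifp_lj_params`.
#' @export
lj_params <- function(well_depth, r_min) {
  stopifnot_scalar(well_depth, "well_depth", positive = TRUE)
  stopifnot_scalar(r_min, "r_min", positive = TRUE)
  structure(list(well_depth = well_depth, r_min = r_min),
            class = "ifp_lj_params")
}

#' Lennard-Jones pair energy
#'
#' The minimum-at-sigma form `eps * ((s/r)^12 - 2 (s/r)^6)`: the well depth is
#' `-eps` at the distance of zero force `r_min`; the potential crosses zero
#' at `2^(-1/6) * r_min`.
#'
#' @param r Distance(s) between the pair (nm); must be > 0.
#' @param lj An [lj_params()] object.
#' @return Energy in kcal/mol (vectorised over `r`).
#' @examples
#' lj <- lj_params(1.48, 0.49)
#' lj_pair_energy(0.49, lj)  # -1.48 at the minimum
#' @export
lj_pair_energy <- function(r, lj) {
  if (any(r <= 0)) abort("`r` must be > 0")
  sr6 <- (lj$r_min / r)^6
  lj$well_depth * (sr6^2 - 2 * sr6)
}

#' Adhesion energy of a subunit model over the substrate lattice
#'
#' Exact pairwise sum of the Lennard-Jones energy between every chain bead and
#' every lattice bead within `cutoff`. Additive over chain beads; zero for
#' beads entirely beyond the cutoff.
#'
#' @param model An `ifp_model`, or an N x 3 coordinate matrix.
#' @param lattice An `ifp_substrate`.
#' @param cutoff Nonbonded cutoff (nm).
#' @return Adhesion energy (kcal/mol, negative when bound).
#' @export
substrate_adhesion_energy <- function(model, lattice, cutoff = 2.5) {
  pos <- if (inherits(model, "ifp_model")) bead_coords(model) else as.matrix(model)
  lp <- as.matrix(lattice$positions)
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  if (xr[1] < lattice$x0 - 1e-9 || xr[2] > lattice$x0 + lattice$extent[1] + 1e-9 ||
      yr[1] < lattice$y0 - 1e-9 || yr[2] > lattice$y0 + lattice$extent[2] + 1e-9) {
    abort("model lies outside the lattice extent")
  }
  tot <- 0
  for (i in seq_len(nrow(pos))) {
    if (pos[i, 3] > cutoff) next
    dx <- lp[, 1] - pos[i, 1]; dy <- lp[, 2] - pos[i, 2]; dz <- lp[, 3] - pos[i, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    sel <- r2 < cutoff^2
    if (any(sel)) tot <- tot + sum(lj_pair_energy(sqrt(r2[sel]), lattice$lj))
  }
  tot
}

#' Convert an adhesion energy density to a per-residue energy
#'
#' Multiplies a surface adhesion energy density gamma (mJ/m^2) by the
#' per-residue adhesion area (nm^2) and converts to molar units via
#' Avogadro's number and 4184 J/kcal. The silica substrate's 50-60 mJ/m^2
#' with a 0.28 nm^2 residue footprint gives 2.01-2.42 kcal/mol.
#'
#' @param gamma Adhesion energy density (mJ/m^2), >= 0.
#' @param area Adhesion area per residue (nm^2), > 0.
#' @return Energy in kcal/mol.
#' @examples
#' gamma_to_per_residue_energy(50, 0.28)  # 2.01
#' gamma_to_per_residue_energy(60, 0.28)  # 2.42
#' @export
gamma_to_per_residue_energy <- function(gamma, area) {
  if (any(gamma < 0)) abort("`gamma` must be >= 0")
  if (any(area <= 0)) abort("`area` must be > 0")
  # mJ/m^2 * nm^2 = 1e-21 J; x N_A / 4184 -> kcal/mol
  gamma * area * 1e-21 * 6.02214076e23 / 4184
}

#' Calibrate the per-pair well depth against a target adhesion well
#'
#' Finds the Lennard-Jones per-pair well depth epsilon such that the minimum
#' over height z of the lattice-summed energy of a single probe bead equals
#' `-target_well`. Because the summed energy is strictly linear in epsilon the
#' solution is exact: the lattice is scanned once at unit epsilon and epsilon
#' is the ratio of the target to the unit-depth well. The probe is placed
#' laterally over a three-fold hollow site near the lattice centre (the
#' deepest site of the triangular lattice).
#'
#' @param target_well Desired total well depth for one bead (kcal/mol), > 0.
#'   For the default chain resolution this is `residues_per_bead * 1.48`.
#' @param pair_r_min Per-pair distance of zero force (nm). The 0.7 nm
#'   default is the smallest value at which the 0.98 nm lattice is
#'   impenetrable to a probe bead (smaller values make the three-fold
#'   hollows attractive channels through the plane and put the energy
#'   minimum inside the surface).
#' @param lattice An `ifp_substrate` (its `lj` well depth is ignored).
#' @param cutoff Nonbonded cutoff (nm).
#' @return The calibrated epsilon (kcal/mol) with attributes `achieved_well`
#'   (the re-measured well, equal to `target_well` up to optimiser tolerance)
#'   and `z_min` (the height of the minimum, nm).
#' @export
calibrate_bead_well_depth <- function(target_well, pair_r_min = 0.7,
                                      lattice, cutoff = 2.5) {
  stopifnot_scalar(target_well, "target_well", positive = TRUE)
  unit <- lattice
  unit$lj <- lj_params(1, pair_r_min)
  probe_xy <- hollow_site(unit)
  scan <- function(z) {
    substrate_adhesion_energy(matrix(c(probe_xy, z), 1), unit, cutoff)
  }
  opt <- optimize(scan, interval = c(0.05, cutoff), tol = 1e-10)
  if (opt$objective >= 0) abort("unit-depth lattice scan found no well")
  eps <- target_well / abs(opt$objective)
  structure(eps, achieved_well = eps * abs(opt$objective), z_min = opt$minimum)
}

# Lateral coordinates of a hollow site close to the lattice centre.
hollow_site <- function(lattice) {
  lp <- as.matrix(lattice$positions)
  ctr <- c(mean(range(lp[, 1])), mean(range(lp[, 2])))
  i <- which.min((lp[, 1] - ctr[1])^2 + (lp[, 2] - ctr[2])^2)
  a <- lattice$spacing
  c(lp[i, 1] + a / 2, lp[i, 2] + a * sqrt(3) / 6)
}

#' Bending constant from a persistence length
#'
#' For a discrete worm-like chain with bond length b, a harmonic bending
#' potential `U = k/2 * theta^2` at each joint reproduces tangent
#' decorrelation with persistence length Lp when `k = Lp * kB * T / b`
#' (kB T = 0.5961 kcal/mol at 300 K). The 25 nm coiled-coil persistence
#' length gives k = 14.90 kcal/mol/rad^2 at 1 nm resolution.
#'
#' @param Lp Persistence length (nm), >= 0.
#' @param bond_length Bond length (nm).
#' @param temperature Temperature (K).
#' @return Bending constant (kcal/mol/rad^2).
#' @export
bending_constant_from_persistence_length <- function(Lp, bond_length = 1,
                                                     temperature = 300) {
  if (any(Lp < 0)) abort("`Lp` must be >= 0")
  Lp * kBT(temperature) / bond_length
}

#' Chain force-field parameters
#'
#' Collects every tunable constant of the coarse-grained chain energy.
#' Defaults: stiff harmonic bonds; coil bending from the 25 nm coiled-coil
#' persistence length; a nearly free hinge at the L12 linker; purely
#' repulsive (WCA) excluded volume at the 2 nm bead diameter; screened
#' Yukawa electrostatics between charged beads with a Debye length for the
#' NaCl assembly condition; soft harmonic inter-dimer crosslinks. The
#' nonbonded cutoff of 2.5 nm keeps a chain started 3 nm above the substrate
#' out of interaction range.
#'
#' @param bond_k Bond stiffness (kcal/mol/nm^2).
#' @param bend_k_coil,bend_k_hinge Bending constants (kcal/mol/rad^2) for
#'   COIL and HINGE joints.
#' @param excluded_eps,excluded_sigma WCA repulsion strength (kcal/mol) and
#'   contact distance (nm).
#' @param dielectric Relative dielectric constant of the implicit solvent.
#' @param debye_length Electrostatic screening length (nm); ~0.8 nm for the
#'   NaCl condition, ~3 nm for low salt.
#' @param cutoff Nonbonded cutoff (nm); must stay below the 3 nm drop height.
#' @param crosslink_k Harmonic crosslink stiffness (kcal/mol/nm^2).
#' @param ca_eps,ca_range Depth (kcal/mol) and range (nm) of the short-range
#'   attraction switched on between coil beads in the calcium environment
#'   mode; `ca_eps` here is the value that mode will use.
#' @param temperature Temperature (K) used for derived defaults.
#' @return A list of class `ifp_forcefield`.
#' @export
forcefield_params <- function(bond_k = 50,
                              bend_k_coil = bending_constant_from_persistence_length(25, 1, temperature),
                              bend_k_hinge = bending_constant_from_persistence_length(1, 1, temperature),
                              excluded_eps = 1,
                              excluded_sigma = 2,
                              dielectric = 78.5,
                              debye_length = 0.8,
                              cutoff = 2.5,
                              crosslink_k = 5,
                              ca_eps = 1.5,
                              ca_range = 1.5,
                              temperature = 300) {
  ff <- list(bond_k = bond_k, bend_k_coil = bend_k_coil,
             bend_k_hinge = bend_k_hinge,
             excluded_eps = excluded_eps, excluded_sigma = excluded_sigma,
             dielectric = dielectric,
             coulomb_prefactor = .coulomb_nm / dielectric,
             debye_length = debye_length, cutoff = cutoff,
             crosslink_k = crosslink_k,
             ca_eps = ca_eps, ca_range = ca_range,
             temperature = temperature)
  for (nm in c("bond_k", "bend_k_coil", "bend_k_hinge", "excluded_eps",
               "crosslink_k")) {
    if (ff[[nm]] < 0) abort(sprintf("`%s` must be >= 0", nm))
  }
  structure(ff, class = "ifp_forcefield")
}

# bending constants per joint, following the joint class
joint_constants <- function(model, ff) {
  ifelse(model$joints$class == "HINGE", ff$bend_k_hinge, ff$bend_k_coil)
}

#' Total energy decomposition of a configuration
#'
#' Evaluates every term of the coarse-grained energy for a model (optionally
#' over a substrate lattice): harmonic bonds and crosslinks (`bonded`),
#' harmonic bending about the straight state (`bending`), WCA excluded volume
#' (`excluded`), screened Coulomb plus any calcium well (`electrostatic`),
#' the substrate Lennard-Jones sum (`adhesion`, 0 without a lattice), and the
#' deposition-pull potential (`external_pull`). `total` is their sum.
#'
#' @param model An `ifp_model`.
#' @param lattice An `ifp_substrate` or `NULL`.
#' @param ff An [forcefield_params()] object.
#' @param pull `NULL`, or a list with `force_per_bead` (kcal/mol/nm) and
#'   `z_threshold` (nm) describing the constant downward deposition force on
#'   beads above the threshold.
#' @param positions Optional N x 3 matrix overriding the model coordinates
#'   (e.g. a trajectory frame).
#' @return A one-row tibble of class `ifp_energy` with the components and
#'   `total`.
#' @export
total_energy <- function(model, lattice = NULL, ff = forcefield_params(),
                         pull = NULL, positions = NULL) {
  pos <- if (is.null(positions)) bead_coords(model) else as.matrix(positions)
  if (nrow(pos) != nrow(model$beads)) {
    abort("`positions` does not match the model bead count")
  }
  b <- model$bonds
  d <- pos[b$j, , drop = FALSE] - pos[b$i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  bonded <- sum(0.5 * ff$bond_k * (r - b$b0)^2)
  if (nrow(model$crosslinks) > 0) {
    cl <- model$crosslinks
    dc <- pos[cl$j, , drop = FALSE] - pos[cl$i, , drop = FALSE]
    rc <- sqrt(rowSums(dc^2))
    bonded <- bonded + sum(0.5 * ff$crosslink_k * (rc - cl$b0)^2)
  }
  jt <- model$joints
  bending <- 0
  if (nrow(jt) > 0) {
    a1 <- pos[jt$i, , drop = FALSE] - pos[jt$j, , drop = FALSE]
    a2 <- pos[jt$k, , drop = FALSE] - pos[jt$j, , drop = FALSE]
    cs <- rowSums(a1 * a2) /
      (sqrt(rowSums(a1^2)) * sqrt(rowSums(a2^2)))
    cs <- pmin(1, pmax(-1, cs))
    dev <- pi - acos(cs)
    bending <- sum(0.5 * joint_constants(model, ff) * dev^2)
  }
  # nonbonded pairs within cutoff, excluding bonded and crosslinked pairs
  n <- nrow(pos)
  excl <- matrix(FALSE, n, n)
  excl[cbind(b$i, b$j)] <- TRUE
  if (nrow(model$crosslinks) > 0) {
    excl[cbind(model$crosslinks$i, model$crosslinks$j)] <- TRUE
  }
  dmat <- as.matrix(stats::dist(pos))
  up <- upper.tri(dmat) & dmat < ff$cutoff & !excl
  excluded <- 0; electro <- 0
  if (any(up)) {
    rr <- dmat[up]
    sel <- rr < ff$excluded_sigma
    if (any(sel) && ff$excluded_eps > 0) {
      sr6 <- (ff$excluded_sigma / rr[sel])^6
      excluded <- sum(ff$excluded_eps * (sr6^2 - 2 * sr6 + 1))
    }
    q <- model$beads$charge
    qq <- outer(q, q)[up]
    electro <- sum(ff$coulomb_prefactor * qq * exp(-rr / ff$debye_length) / rr)
    if (!is.null(ff$ca_on) && isTRUE(ff$ca_on)) {
      electro <- electro - sum(ff$ca_eps * exp(-(rr / ff$ca_range)^2))
    }
  }
  adhesion <- if (is.null(lattice)) 0 else {
    substrate_adhesion_energy(pos, lattice, ff$cutoff)
  }
  external_pull <- 0
  if (!is.null(pull)) {
    above <- pos[, 3] > pull$z_threshold
    external_pull <- sum(pull$force_per_bead * (pos[above, 3] - pull$z_threshold))
  }
  out <- tibble(bonded = bonded, bending = bending, excluded = excluded,
                electrostatic = electro, adhesion = adhesion,
                external_pull = external_pull)
  out$total <- rowSums(out)
  class(out) <- c("ifp_energy", class(out))
  out
}
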