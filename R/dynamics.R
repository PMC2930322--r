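# Overdamped Langevin sampling of subunit conformations in solution and
# during deposition onto the adhesive substrate.
#
# Reduced units: lengths nm, energies kcal/mol, friction gamma = 1 per bead,
# so time is gamma nm^2 / (kcal/mol) and a free bead has diffusion constant
# kB T / gamma = 0.596 nm^2 per time unit at 300 K. Temperature enters only
# through the fluctuation-dissipation noise amplitude sqrt(2 kB T dt / gamma).

#' Simulation configuration
#'
#' @param n_steps Number of integration steps.
#' @param timestep Integration step (reduced time). `NULL` picks 1e-3 in
#'   solution and 1e-4 over the substrate (whose adhesion well is the
#'   stiffest interaction).
#' @param friction Bead friction coefficient (reduced units).
#' @param temperature Temperature (K).
#' @param seed Integer seed; trajectories are bit-reproducible given the seed.
#' @param pull_force_per_residue Deposition pull (kcal/mol/Angstrom per
#'   residue) applied to beads above `pull_z_threshold`; scaled by each
#'   bead's `residues_per_bead` and converted to per-nm units internally.
#' @param pull_z_threshold Height (nm) above which the pull acts.
#' @param environment One of `"solution"`, `"substrate"`,
#'   `"substrate+calcium"`, `"substrate+glutaraldehyde"`.
#' @param record_every Record a frame every this many steps.
#' @return A list of class `ifp_sim_config`.
#' @export
sim_config <- function(n_steps = 2e5, timestep = NULL, friction = 1,
                       temperature = 300, seed = 1,
                       pull_force_per_residue = 0.0012,
                       pull_z_threshold = 5,
                       environment = c("solution", "substrate",
                                       "substrate+calcium",
                                       "substrate+glutaraldehyde"),
                       record_every = max(1, round(n_steps / 400))) {
  environment <- match.arg(environment)
  if (!is.null(timestep)) stopifnot_scalar(timestep, "timestep", positive = TRUE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  structure(list(n_steps = n_steps, timestep = timestep, friction = friction,
                 temperature = temperature, seed = as.integer(seed),
                 pull_force_per_residue = pull_force_per_residue,
                 pull_z_threshold = pull_z_threshold,
                 environment = environment,
                 record_every = as.integer(record_every)),
            class = "ifp_sim_config")
}

uses_substrate <- function(config) {
  startsWith(config$environment, "substrate")
}

#' Per-bead deposition pull forces
#'
#' The deposition protocol applies a constant downward force to every bead
#' whose vertical coordinate exceeds the threshold (5 nm by default), gently
#' settling the subunit onto the substrate; beads below the threshold feel
#' nothing.
#'
#' @param positions N x 3 coordinate matrix (nm).
#' @param config An [sim_config()].
#' @param residues_per_bead Residues represented per bead (scales the force).
#' @return N x 3 matrix of forces (kcal/mol/nm); rows are `(0, 0, -f)` for
#'   beads above the threshold and zero otherwise.
#' @export
apply_deposition_pull <- function(positions, config,
                                  residues_per_bead = 18) {
  pos <- as.matrix(positions)
  f <- config$pull_force_per_residue * residues_per_bead * 10  # /A -> /nm
  out <- matrix(0, nrow(pos), 3)
  out[pos[, 3] > config$pull_z_threshold, 3] <- -f
  out
}

#' Apply an environment mode to a model and force field
#'
#' `solution` and `substrate` leave both untouched. `substrate+calcium`
#' switches on the short-range attraction between nonbonded coil beads
#' (depth `ff$ca_eps`, range `ff$ca_range`), standing in for divalent-ion
#' bridging. `substrate+glutaraldehyde` converts every nonbonded bead pair
#' currently closer than `capture_radius` into a permanent harmonic
#' crosslink at its current distance, once, at invocation (covalent
#' fixation of whatever conformation the subunit has).
#'
#' @param model An `ifp_model`.
#' @param ff An [forcefield_params()].
#' @param mode Environment string as in [sim_config()].
#' @param capture_radius Glutaraldehyde capture radius (nm).
#' @return A list with elements `model` and `ff`.
#' @export
apply_environment_mode <- function(model, ff, mode,
                                   capture_radius = 1.5) {
  modes <- c("solution", "substrate", "substrate+calcium",
             "substrate+glutaraldehyde")
  if (!mode %in% modes) abort(sprintf("unknown environment mode '%s'", mode))
  if (mode == "substrate+calcium") {
    ff$ca_on <- TRUE
  } else if (mode == "substrate+glutaraldehyde") {
    pos <- bead_coords(model)
    n <- nrow(pos)
    dmat <- as.matrix(stats::dist(pos))
    excl <- matrix(FALSE, n, n)
    excl[cbind(model$bonds$i, model$bonds$j)] <- TRUE
    excl[cbind(model$bonds$j, model$bonds$i)] <- TRUE
    if (nrow(model$crosslinks) > 0) {
      excl[cbind(model$crosslinks$i, model$crosslinks$j)] <- TRUE
      excl[cbind(model$crosslinks$j, model$crosslinks$i)] <- TRUE
    }
    hit <- which(upper.tri(dmat) & dmat < capture_radius & !excl,
                 arr.ind = TRUE)
    if (nrow(hit) > 0) {
      new <- tibble(i = hit[, 1], j = hit[, 2],
                    b0 = dmat[hit])
      model$crosslinks <- bind_rows(model$crosslinks, new)
    }
  }
  list(model = model, ff = ff)
}

#' Run an overdamped Langevin simulation
#'
#' Integrates the chain beads under the deterministic forces of the full
#' energy model plus fluctuation-dissipation thermal noise. Substrate beads
#' are immobile; their force on the chain is interpolated from a periodic
#' table built by exact lattice summation at run start. With a substrate the
#' model must start with its lowest bead at 3 nm (beyond the nonbonded
#' cutoff) unless `check_start = FALSE`.
#'
#' @param model An `ifp_model`.
#' @param lattice An `ifp_substrate` (required for substrate environments).
#' @param ff An [forcefield_params()].
#' @param config An [sim_config()].
#' @param zero_temperature If `TRUE`, suppress thermal noise (gradient
#'   descent limit; used for energy-minimisation checks).
#' @param check_start Verify the 3 nm starting height over a substrate.
#' @return An object of class `ifp_trajectory`: `frames` (N x 3 x F array),
#'   `times`, `model`, `lattice`, `ff`, `config`, `seed`.
#' @export
run_simulation <- function(model, lattice = NULL, ff = forcefield_params(),
                           config = sim_config(), zero_temperature = FALSE,
                           check_start = TRUE) {
  sub <- uses_substrate(config)
  if (sub && is.null(lattice)) abort("substrate environment needs a lattice")
  if (!sub) lattice <- NULL
  env <- apply_environment_mode(model, ff, config$environment)
  model <- env$model; ff <- env$ff
  pos <- bead_coords(model)
  if (sub && check_start && abs(min(pos[, 3]) - 3) > 0.51) {
    abort("deposit from a start with minimum bead height 3 nm (or set check_start = FALSE)")
  }
  dt <- config$timestep
  if (is.null(dt)) dt <- if (sub) 1e-4 else 1e-3
  rpb <- model$beads$residues_per_bead[1]
  par <- list(dt = dt, friction = config$friction,
              kBT = kBT(config$temperature),
              bond_k = ff$bond_k, crosslink_k = ff$crosslink_k,
              excluded_eps = ff$excluded_eps, excluded_sigma = ff$excluded_sigma,
              coulomb_prefactor = ff$coulomb_prefactor,
              debye_length = ff$debye_length, cutoff = ff$cutoff,
              ca_eps = if (isTRUE(ff$ca_on)) ff$ca_eps else 0,
              ca_range = ff$ca_range,
              pull_force_per_bead = if (sub) config$pull_force_per_residue * rpb * 10 else 0,
              pull_z_threshold = config$pull_z_threshold)
  sub_list <- list()
  if (sub) {
    margin <- ff$cutoff + 0.6
    sub_list <- list(spacing = lattice$spacing, x0 = lattice$x0, y0 = lattice$y0,
                     eps = lattice$lj$well_depth, sigma = lattice$lj$r_min,
                     cutoff = ff$cutoff,
                     xlo = lattice$x0 + margin,
                     xhi = lattice$x0 + lattice$extent[1] - margin,
                     ylo = lattice$y0 + margin,
                     yhi = lattice$y0 + lattice$extent[2] - margin)
    if (any(pos[, 1] < sub_list$xlo | pos[, 1] > sub_list$xhi |
            pos[, 2] < sub_list$ylo | pos[, 2] > sub_list$yhi)) {
      abort("model lies outside the lattice extent (allow a cutoff margin)")
    }
  }
  res <- cg_run_cpp(pos,
                    as.matrix(model$bonds[, c("i", "j")]) - 1L,
                    model$bonds$b0,
                    as.matrix(model$joints[, c("i", "j", "k")]) - 1L,
                    joint_constants(model, ff),
                    as.matrix(model$crosslinks[, c("i", "j"), drop = FALSE]) - 1L,
                    model$crosslinks$b0,
                    model$beads$charge,
                    par, sub_list,
                    config$n_steps, config$record_every,
                    as.numeric(config$seed), zero_temperature)
  if (res$failed_step >= 0) {
    if (isTRUE(res$out_of_extent)) {
      abort(sprintf("bead left the lattice extent at step %.0f; enlarge the substrate",
                    res$failed_step))
    }
    abort(sprintf("force overflow at step %.0f; reduce the timestep",
                  res$failed_step))
  }
  structure(list(frames = res$frames, times = res$times, model = model,
                 lattice = lattice, ff = ff, config = config,
                 timestep = dt, seed = config$seed),
            class = "ifp_trajectory")
}

#' Number of frames in a trajectory
#' @param traj An `ifp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Coordinates of one trajectory frame
#' @param traj An `ifp_trajectory`.
#' @param frame Frame index (1-based); defaults to the last frame.
#' @return N x 3 matrix (nm).
#' @export
frame_positions <- function(traj, frame = n_frames(traj)) {
  traj$frames[, , frame]
}

#' @export
print.ifp_trajectory <- function(x, ...) {
  cat(sprintf("<ifp_trajectory: %s, %d beads, %d frames, dt %.2g, seed %d, %s>\n",
              x$model$kind, dim(x$frames)[1], n_frames(x),
              x$timestep, x$seed, x$config$environment))
  invisible(x)
}

#' Per-frame conformational metrics of a trajectory
#'
#' @param x An `ifp_trajectory`.
#' @param energies Also evaluate the energy breakdown per frame (slower).
#' @param ... Unused.
#' @return A tibble with `frame`, `time`, `end_to_end`, `rg`, `min_z`,
#'   `mean_z`, and the energy components if requested.
#' @export
tidy.ifp_trajectory <- function(x, energies = FALSE, ...) {
  nf <- n_frames(x)
  pull <- NULL
  if (uses_substrate(x$config)) {
    pull <- list(force_per_bead = x$config$pull_force_per_residue *
                   x$model$beads$residues_per_bead[1] * 10,
                 z_threshold = x$config$pull_z_threshold)
  }
  rows <- purrr::map_dfr(seq_len(nf), function(f) {
    p <- frame_positions(x, f)
    ctr <- colMeans(p)
    out <- tibble(frame = f, time = x$times[f],
                  end_to_end = end_to_end_length(x$model, positions = p),
                  rg = sqrt(mean(rowSums(sweep(p, 2, ctr)^2))),
                  min_z = min(p[, 3]), mean_z = mean(p[, 3]))
    if (energies) {
      e <- total_energy(x$model, x$lattice, x$ff, pull = pull, positions = p)
      out <- dplyr::bind_cols(out, e)
    }
    out
  })
  rows
}

#' One-row summary of a trajectory
#'
#' @param x An `ifp_trajectory`.
#' @param window Trailing fraction of frames used for the means.
#' @param ... Unused.
#' @return A tibble with bead/frame counts, trailing-window means of the
#'   end-to-end length and gyration radius, and the convergence flag.
#' @export
glance.ifp_trajectory <- function(x, window = 0.3, ...) {
  tl <- tidy(x)
  nf <- nrow(tl)
  keep <- tl[tl$frame > (1 - window) * nf, ]
  conv <- check_convergence(x, window = max(10, floor(window * nf)))
  tibble(n_beads = dim(x$frames)[1], n_frames = nf,
         environment = x$config$environment, seed = x$seed,
         mean_end_to_end = mean(keep$end_to_end),
         sd_end_to_end = sd(keep$end_to_end),
         mean_rg = mean(keep$rg),
         converged = conv$converged)
}

#' Convergence check on the trailing RMSD series
#'
#' Computes the Kabsch RMSD of every frame to a reference frame and declares
#' the run converged when, over the trailing `window` frames, the RMSD drift
#' (fitted slope times the window span) and the fluctuation (sd about the
#' fit) both fall below their tolerances.
#'
#' @param traj An `ifp_trajectory`.
#' @param reference_frame Frame the RMSD is measured against (default last).
#' @param window Number of trailing frames examined.
#' @param max_drift Allowed drift over the window (nm).
#' @param max_fluct Allowed fluctuation (nm).
#' @return A list with `converged`, the `rmsd` tibble (frame, time, rmsd),
#'   `drift` and `fluct`.
#' @export
check_convergence <- function(traj, reference_frame = n_frames(traj),
                              window = max(10, floor(n_frames(traj) / 4)),
                              max_drift = 0.75, max_fluct = 0.75) {
  nf <- n_frames(traj)
  if (window > nf) abort("`window` longer than the trajectory")
  ref <- frame_positions(traj, reference_frame)
  rmsd <- vapply(seq_len(nf), function(f) {
    kabsch_rmsd(frame_positions(traj, f), ref)
  }, numeric(1))
  tl <- tibble(frame = seq_len(nf), time = traj$times, rmsd = rmsd)
  tail_tl <- tl[tl$frame > nf - window, ]
  if (sd(tail_tl$rmsd) < 1e-12) {
    drift <- 0; fluct <- 0
  } else {
    fit <- lm(rmsd ~ time, data = tail_tl)
    drift <- abs(coef(fit)[2]) * diff(range(tail_tl$time))
    fluct <- sd(stats::residuals(fit))
  }
  list(converged = drift <= max_drift && fluct <= max_fluct,
       rmsd = tl, drift = unname(drift), fluct = fluct)
}

#' Place a model above the substrate for deposition
#'
#' Centres the model laterally on the lattice and sets its lowest bead to
#' `height`. For a tetramer the azimuthal orientation about the long axis is
#' random (subunits tumble in solution before they meet the surface), drawn
#' from the supplied seed.
#'
#' @param model An `ifp_model`.
#' @param height Starting height of the lowest bead (nm).
#' @param seed Seed for the azimuthal roll (`NULL` keeps the built pose).
#' @return The repositioned model.
#' @export
place_for_deposition <- function(model, height = 3, seed = NULL) {
  pos <- bead_coords(model)
  if (!is.null(seed)) {
    phi <- with_local_seed(seed, runif(1, 0, 2 * pi))
    ctr <- colMeans(pos)
    rel <- sweep(pos, 2, ctr)
    rot <- matrix(c(1, 0, 0,
                    0, cos(phi), -sin(phi),
                    0, sin(phi), cos(phi)), 3, 3, byrow = TRUE)
    pos <- sweep(rel %*% t(rot), 2, ctr, `+`)
  }
  pos[, 1] <- pos[, 1] - mean(range(pos[, 1]))
  pos[, 2] <- pos[, 2] - mean(range(pos[, 2]))
  pos[, 3] <- pos[, 3] - min(pos[, 3]) + height
  model$beads$x <- pos[, 1]; model$beads$y <- pos[, 2]; model$beads$z <- pos[, 3]
  model
}
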