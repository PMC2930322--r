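# Experiment recipes and file I/O: end-to-end desk-scale reproductions of
# the study's computational figures, plus XYZ/PDB/TIFF/CSV writers.

#' Built-in experiment recipes
#'
#' * `calibration_report` - adhesion-density conversion and the per-bead
#'   well-depth calibration, with the brute-force re-scan residual.
#' * `fig11_dimer`, `fig11_tetramer` - solution vs on-substrate Langevin
#'   runs over the given seeds, reporting trailing-window means of the
#'   end-to-end length, projection area and coarse-grained SASA.
#' * `afm_fig5` - vimentin and K5/K14 NaCl synthetic scenes through the
#'   morphometry pipeline.
#' * `afm_fig8` - K5/K14 NaCl, glutaraldehyde and CaCl2 scenes compared.
#'
#' @return Character vector of recipe names.
#' @export
recipe_names <- function() {
  c("calibration_report", "fig11_dimer", "fig11_tetramer",
    "afm_fig5", "afm_fig8")
}

#' Run a named experiment recipe
#'
#' Executes one of the built-in desk-scale recipes (see [recipe_names()])
#' and returns a report object; re-running with identical seeds reproduces
#' every number. When `outdir` is given, all tables are written as CSV/JSON
#' alongside a provenance record (recipe, seeds, parameter hash).
#'
#' @param name Recipe name.
#' @param seeds Integer seeds (one run per seed where the recipe samples).
#' @param outdir Output directory or `NULL`.
#' @param n_steps Override the per-run step count (`NULL` = recipe default).
#' @param n_subunits Objects per synthetic AFM scene.
#' @return A list of class `ifp_report` with elements `name`, `report`
#'   (tibble), `details` (list), `seeds`, `hash`.
#' @export
run_recipe <- function(name, seeds = 1:3, outdir = NULL, n_steps = NULL,
                       n_subunits = 300) {
  if (!name %in% recipe_names()) {
    abort(sprintf("unknown recipe '%s' (see recipe_names())", name))
  }
  res <- switch(
    name,
    calibration_report = recipe_calibration(),
    fig11_dimer = recipe_fig11("dimer", seeds, n_steps),
    fig11_tetramer = recipe_fig11("tetramer", seeds, n_steps),
    afm_fig5 = recipe_afm(c("vimentin_NaCl", "K5K14_NaCl"), seeds[1],
                          n_subunits),
    afm_fig8 = recipe_afm(c("K5K14_NaCl", "K5K14_glutaraldehyde",
                            "K5K14_CaCl2"), seeds[1], n_subunits)
  )
  out <- structure(list(name = name, report = res$report,
                        details = res$details, seeds = seeds,
                        hash = rlang::hash(list(name, seeds, n_steps,
                                                n_subunits))),
                   class = "ifp_report")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

recipe_calibration <- function(rpb = 18) {
  lat <- build_substrate(width = 24, depth = 24)
  per_res <- gamma_to_per_residue_energy(c(50, 60), 0.28)
  target <- 1.48 * rpb
  eps <- calibrate_bead_well_depth(target, 0.7, lat)
  report <- tibble(
    quantity = c("per-residue adhesion (50 mJ/m^2)",
                 "per-residue adhesion (60 mJ/m^2)",
                 "per-bead target well", "calibrated pair epsilon",
                 "achieved well", "residual"),
    value = c(per_res, target, as.numeric(eps),
              attr(eps, "achieved_well"),
              attr(eps, "achieved_well") - target),
    units = c("kcal/mol", "kcal/mol", "kcal/mol", "kcal/mol", "kcal/mol",
              "kcal/mol"))
  list(report = report, details = list(z_min = attr(eps, "z_min")))
}

# one deposition or solution run with the standard study protocol
study_run <- function(kind, environment, seed, n_steps = NULL) {
  model <- if (kind == "dimer") build_dimer() else build_tetramer()
  ff <- forcefield_params()
  if (environment == "solution") {
    cfg <- sim_config(n_steps = if (is.null(n_steps)) 2.5e6 else n_steps,
                      seed = seed, environment = "solution")
    return(run_simulation(model, ff = ff, config = cfg))
  }
  lat <- deposition_lattice(model)
  model <- place_for_deposition(model, 3, seed = seed)
  cfg <- sim_config(n_steps = if (is.null(n_steps)) 1.2e6 else n_steps,
                    seed = seed, environment = environment)
  run_simulation(model, lat, ff, cfg)
}

# lattice sized for a deposited subunit with drift + cutoff margin,
# calibrated so each bead's adhesion well is residues_per_bead x 1.48 kcal/mol
deposition_lattice <- function(model, margin = 14, rpb = 18,
                               pair_r_min = 0.7) {
  span <- diff(range(model$beads$x))
  lat <- build_substrate(width = span + 2 * margin, depth = 2 * margin + 6)
  eps <- calibrate_bead_well_depth(1.48 * rpb, pair_r_min, lat)
  lat$lj <- lj_params(as.numeric(eps), pair_r_min)
  lat
}

recipe_fig11 <- function(kind, seeds, n_steps) {
  grid <- tidyr::expand_grid(environment = c("solution", "substrate"),
                             seed = seeds)
  runs <- purrr::pmap(grid, function(environment, seed) {
    traj <- study_run(kind, environment, seed, n_steps)
    met <- trailing_metrics(traj)
    dplyr::bind_cols(tibble(environment = environment, seed = seed), met)
  })
  per_run <- bind_rows(runs)
  report <- per_run |>
    tidyr::pivot_longer(c("end_to_end", "projection_area", "sasa"),
                        names_to = "metric") |>
    group_by(.data$environment, .data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") |>
    mutate(kind = kind, .before = 1)
  list(report = report, details = list(per_run = per_run))
}

# trailing-window (last 30% of frames) means of the conformational metrics
trailing_metrics <- function(traj, window = 0.3, stride = 4) {
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  frames <- frames[frames > (1 - window) * nf]
  frames <- frames[seq(1, length(frames), by = stride)]
  vals <- purrr::map_dfr(frames, function(f) {
    p <- frame_positions(traj, f)
    tibble(end_to_end = end_to_end_length(traj$model, positions = p),
           projection_area = projection_area(traj$model, positions = p,
                                             grid_resolution = 0.5),
           sasa = cg_sasa(traj$model, positions = p, n_sphere_points = 146))
  })
  summarise(vals, across(dplyr::everything(), mean))
}

recipe_afm <- function(presets, seed, n_subunits) {
  rows <- purrr::map(presets, function(p) {
    img <- generate_scene(p, n_subunits = n_subunits, seed = seed)
    img <- add_noise(render_tip_dilation(img, 3), 0.03, seed = seed + 1000L)
    seg <- measure_afm_image(img)
    sm <- summarize_objects(seg)
    ad <- area_probability_distribution(seg)
    mutate(sm, preset = p, fitted_mean_area = ad$fitted_mean, .before = 1)
  })
  list(report = bind_rows(rows), details = list(seed = seed))
}

#' @export
print.ifp_report <- function(x, ...) {
  cat(sprintf("<ifp_report: %s (seeds %s, hash %s)>\n", x$name,
              paste(x$seeds, collapse = ","), substr(x$hash, 1, 8)))
  print(x$report)
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(outdir, report$name)
  write.csv(report$report, paste0(base, "_report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(recipe = report$name, seeds = report$seeds, hash = report$hash),
    paste0(base, "_provenance.json"), auto_unbox = TRUE)
  invisible(report)
}

# ---------------------------------------------------------------------------
# Structure and trajectory writers
# ---------------------------------------------------------------------------

#' Write a model or trajectory as (multi-frame) XYZ
#'
#' One pseudo-atom per bead, element by segment (C for coil, N for linker).
#' Trajectories write every recorded frame.
#'
#' @param x An `ifp_model` or `ifp_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  model <- if (inherits(x, "ifp_trajectory")) x$model else x
  el <- ifelse(model$beads$segment == "LINKER", "N", "C")
  frames <- if (inherits(x, "ifp_trajectory")) {
    lapply(seq_len(n_frames(x)), function(f) frame_positions(x, f))
  } else list(bead_coords(model))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    p <- frames[[f]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' @param path XYZ file written by [write_xyz()] (or compatible).
#' @return A list of N x 3 coordinate matrices, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), n, 3)
    i <- i + 2 + n
  }
  frames
}

#' Write per-frame trajectory metrics (and energies) to CSV
#'
#' One row per recorded frame with time, end-to-end length, gyration
#' radius and heights; with `energies = TRUE` the full energy breakdown is
#' appended. The run configuration (seed included) is echoed to
#' `<path>.json` so every output is traceable to its seed.
#'
#' @param traj An `ifp_trajectory`.
#' @param path Output CSV path.
#' @param energies Include the per-frame energy decomposition (slower).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, energies = FALSE) {
  write.csv(tidy(traj, energies = energies), path, row.names = FALSE)
  cfg <- traj$config
  jsonlite::write_json(
    list(environment = cfg$environment, n_steps = cfg$n_steps,
         timestep = traj$timestep, temperature = cfg$temperature,
         friction = cfg$friction, seed = traj$seed,
         record_every = cfg$record_every, kind = traj$model$kind),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a model as a CA-trace PDB
#'
#' One CA pseudo-atom per bead; chain A/B per dimer path, so the file loads
#' in any structure viewer.
#'
#' @param model An `ifp_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  p <- bead_coords(model) * 10  # nm -> Angstrom
  ch <- c("A", "B")[model$beads$chain]
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(p)), ch, seq_len(nrow(p)), p[, 1], p[, 2], p[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an AFM image as 32-bit float TIFF (+ JSON sidecar)
#'
#' Heights are stored as 32-bit floats scaled into the TIFF's unit range;
#' the scale factor, pixel size, preset, seed and provenance live in a JSON
#' sidecar (`<path>.json`), which plain TIFF tags do not hold portably.
#'
#' @param image An `ifp_afm_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_afm_tiff <- function(image, path) {
  m <- image$heights
  lo <- min(m, 0)
  scale <- max(m - lo, 1e-12)
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size = image$pixel_size, preset = image$preset,
         seed = image$seed, height_scale = scale, height_offset = lo,
         provenance = image$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AFM image written by [write_afm_tiff()]
#'
#' Any single-channel float TIFF loads; the JSON sidecar restores the pixel
#' size (1 nm assumed when absent).
#'
#' @param path TIFF path.
#' @return An `ifp_afm_image` (without ground truth).
#' @export
read_afm_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  meta <- list(pixel_size = 1, preset = NA_character_, seed = NA,
               height_scale = 1, height_offset = 0, provenance = list())
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- utils::modifyList(meta, jsonlite::read_json(side))
  m <- m * meta$height_scale + meta$height_offset
  structure(list(heights = m, pixel_size = meta$pixel_size,
                 preset = meta$preset, seed = meta$seed,
                 ground_truth = NULL, masks = NULL,
                 filament_mask = integer(),
                 provenance = meta$provenance),
            class = "ifp_afm_image")
}

#' Load a recipe/parameter configuration file
#'
#' JSON loads through jsonlite; a `.yaml`/`.yml` file loads through the yaml
#' package when it is installed.
#'
#' @param path Config path.
#' @return A named list.
#' @export
load_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs need the 'yaml' package; use JSON instead")
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Plot trajectory metrics over time
#'
#' @param object An `ifp_trajectory`.
#' @param ... Unused.
#' @return A ggplot of end-to-end length and gyration radius vs time.
#' @export
autoplot.ifp_trajectory <- function(object, ...) {
  tl <- tidy(object) |>
    tidyr::pivot_longer(c("end_to_end", "rg"), names_to = "metric")
  ggplot2::ggplot(tl, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (reduced units)", y = "length (nm)",
                  title = sprintf("%s, %s", object$model$kind,
                                  object$config$environment))
}

#' Plot a subunit model projected on the xy plane
#'
#' @param object An `ifp_model`.
#' @param ... Unused.
#' @return A ggplot of the bead chains.
#' @export
autoplot.ifp_model <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y,
                                   colour = factor(.data$chain),
                                   group = .data$chain)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", colour = "dimer",
                  title = object$kind)
}
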