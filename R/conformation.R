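# Conformational observables: end-to-end length, Kabsch RMSD, projection
# area, coarse-grained SASA, worm-like-chain analytics.

#' End-to-end length of a subunit
#'
#' For a dimer, the distance between its terminal beads. For a tetramer the
#' rod length is taken as the maximum distance between terminal beads of the
#' two dimer paths (the intuitive "length of the rod"; the observable is not
#' otherwise defined for a two-chain object).
#'
#' @param model An `ifp_model`.
#' @param positions Optional N x 3 matrix overriding model coordinates.
#' @return Length in nm.
#' @export
end_to_end_length <- function(model, positions = NULL) {
  pos <- if (is.null(positions)) bead_coords(model) else as.matrix(positions)
  if (nrow(pos) < 2) abort("need at least 2 beads")
  term <- chain_termini(model)
  ids <- unique(c(term$first, term$last))
  if (length(ids) == 2) {
    return(sqrt(sum((pos[ids[1], ] - pos[ids[2], ])^2)))
  }
  max(stats::dist(pos[ids, , drop = FALSE]))
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Translates both coordinate sets to their centroids and rotates `coords_a`
#' onto `coords_b` with the SVD-based Kabsch algorithm (proper rotations
#' only; no reflection), returning the residual root-mean-square deviation.
#' All beads are weighted equally.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices with equal N.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) abort("coordinate sets differ in size")
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((a %*% t(rot) - b)^2)))
}

# principal-axis frame with deterministic handling of degenerate cases:
# near-equal or vanishing eigenvalues fall back to the lexicographic axis
# order so collinear chains still get a reproducible frame
principal_frame <- function(pos) {
  ctr <- colMeans(pos)
  rel <- sweep(pos, 2, ctr)
  cv <- crossprod(rel) / nrow(rel)
  eg <- eigen(cv, symmetric = TRUE)
  vec <- eg$vectors
  if (eg$values[2] < 1e-9 * max(eg$values[1], 1e-12)) {
    a1 <- vec[, 1]
    ref <- if (abs(a1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a2 <- ref - sum(ref * a1) * a1
    a2 <- a2 / sqrt(sum(a2^2))
    a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
            a1[3] * a2[1] - a1[1] * a2[3],
            a1[1] * a2[2] - a1[2] * a2[1])
    vec <- cbind(a1, a2, a3)
  }
  list(center = ctr, axes = vec, values = eg$values)
}

#' Projected footprint area of a model
#'
#' Rasterises the union of bead disks onto a principal-axis plane and counts
#' occupied cells. By default the projection plane is spanned by the first
#' two principal axes (normal = third axis), the maximal-footprint
#' convention that tracks how far the subunit has spread; `plane =
#' "first_axis"` instead projects along the first principal axis (the
#' minimal cross-section, the literal reading of the alternative
#' convention).
#'
#' @param model An `ifp_model`.
#' @param grid_resolution Raster cell size (nm); must not exceed the bead
#'   radius.
#' @param plane `"max_footprint"` (default) or `"first_axis"`.
#' @param positions Optional N x 3 matrix overriding model coordinates.
#' @return Area in nm^2.
#' @export
projection_area <- function(model, grid_resolution = 0.25,
                            plane = c("max_footprint", "first_axis"),
                            positions = NULL) {
  plane <- match.arg(plane)
  pos <- if (is.null(positions)) bead_coords(model) else as.matrix(positions)
  rad <- model$beads$radius
  if (grid_resolution > min(rad)) abort("`grid_resolution` must be <= bead radius")
  pf <- principal_frame(pos)
  axes <- if (plane == "max_footprint") pf$axes[, 1:2] else pf$axes[, 2:3]
  uv <- sweep(pos, 2, pf$center) %*% axes
  rasterized_disk_area(uv, rad, grid_resolution)
}

# area of the union of disks at 2D centres `uv` with radii `rad`
rasterized_disk_area <- function(uv, rad, h) {
  rmax <- max(rad)
  u0 <- min(uv[, 1]) - rmax - h; u1 <- max(uv[, 1]) + rmax + h
  v0 <- min(uv[, 2]) - rmax - h; v1 <- max(uv[, 2]) + rmax + h
  nu <- ceiling((u1 - u0) / h); nv <- ceiling((v1 - v0) / h)
  occ <- matrix(FALSE, nu, nv)
  for (b in seq_len(nrow(uv))) {
    r <- rad[if (length(rad) > 1) b else 1]
    iu <- floor((uv[b, 1] - r - u0) / h):ceiling((uv[b, 1] + r - u0) / h)
    iv <- floor((uv[b, 2] - r - v0) / h):ceiling((uv[b, 2] + r - v0) / h)
    iu <- iu[iu >= 1 & iu <= nu]; iv <- iv[iv >= 1 & iv <= nv]
    cu <- u0 + (iu - 0.5) * h; cv <- v0 + (iv - 0.5) * h
    d2 <- outer((cu - uv[b, 1])^2, (cv - uv[b, 2])^2, `+`)
    occ[iu, iv] <- occ[iu, iv] | (d2 <= r^2)
  }
  sum(occ) * h^2
}

# deterministic Fibonacci sphere point set
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Coarse-grained solvent-accessible surface area
#'
#' Shrake-Rupley-style spherical point sampling over the beads: points are
#' placed on each bead's expanded sphere (radius + probe) using a
#' deterministic Fibonacci lattice and counted as accessible when outside
#' every other bead's expanded sphere.
#'
#' @param model An `ifp_model`.
#' @param probe_radius Probe radius (nm), >= 0.
#' @param n_sphere_points Sample points per bead.
#' @param positions Optional N x 3 matrix overriding model coordinates.
#' @return Area in nm^2.
#' @export
cg_sasa <- function(model, probe_radius = 0, n_sphere_points = 362,
                    positions = NULL) {
  if (probe_radius < 0) abort("`probe_radius` must be >= 0")
  pos <- if (is.null(positions)) bead_coords(model) else as.matrix(positions)
  rad <- model$beads$radius + probe_radius
  if (length(rad) == 1) rad <- rep(rad, nrow(pos))
  sph <- fibonacci_sphere(n_sphere_points)
  total <- 0
  for (b in seq_len(nrow(pos))) {
    pts <- sweep(sph * rad[b], 2, pos[b, ], `+`)
    acc <- rep(TRUE, nrow(pts))
    for (o in seq_len(nrow(pos))) {
      if (o == b) next
      d2 <- (pos[o, 1] - pos[b, 1])^2 + (pos[o, 2] - pos[b, 2])^2 +
        (pos[o, 3] - pos[b, 3])^2
      if (d2 >= (rad[b] + rad[o])^2) next
      pd2 <- (pts[, 1] - pos[o, 1])^2 + (pts[, 2] - pos[o, 2])^2 +
        (pts[, 3] - pos[o, 3])^2
      # strictly interior points are buried; points exactly on a shared
      # boundary (fully coincident beads) count once, for the lowest index
      buried <- pd2 < rad[o]^2 * (1 - 1e-9)
      if (o < b) buried <- buried | pd2 <= rad[o]^2 * (1 + 1e-9)
      acc <- acc & !buried
      if (!any(acc)) break
    }
    total <- total + 4 * pi * rad[b]^2 * mean(acc)
  }
  total
}

#' Mean angle between worm-like-chain segment end tangents
#'
#' For a 3D worm-like chain the tangent autocorrelation decays as
#' `<t(0).t(L)> = exp(-L/Lp)`; the mean angle between the tangents at the
#' two ends of a segment of length L is `acos(exp(-L/Lp))`. A 25 nm
#' coiled-coil segment at the 25 nm coiled-coil persistence length gives
#' about 70 degrees, which is why IF subunits are visibly flexible.
#'
#' @param L Segment length (nm), >= 0.
#' @param Lp Persistence length (nm), > 0.
#' @return Angle in degrees.
#' @examples
#' wlc_mean_tangent_angle(25, 25)  # 68.4 degrees
#' @export
wlc_mean_tangent_angle <- function(L, Lp) {
  if (any(L < 0)) abort("`L` must be >= 0")
  if (any(Lp <= 0)) abort("`Lp` must be > 0")
  acos(exp(-L / Lp)) * 180 / pi
}

#' Estimate the persistence length from a trajectory
#'
#' Pools bond tangent correlations `<t(s) . t(s + delta)>` over the trailing
#' frames of an equilibrated trajectory and fits the exponential decay
#' `exp(-delta b / Lp)` by log-linear regression over lags 1..`max_lag`.
#' Only bonds whose beads both carry a matching segment label are used
#' (`segment_label = NULL` uses all bonds).
#'
#' @param traj An `ifp_trajectory`.
#' @param segment_label Segment prefix to keep (e.g. `"COIL"`), or `NULL`.
#' @param max_lag Maximum bond-count lag in the fit.
#' @param discard_frac Leading fraction of frames discarded as equilibration.
#' @return Persistence length (nm). A chain too straight to show decay
#'   (rigid limit) returns `Inf` with attribute `flag = "ge_contour"`.
#' @export
estimate_persistence_length <- function(traj, segment_label = "COIL",
                                        max_lag = 10, discard_frac = 0.2) {
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  frames <- frames[frames > discard_frac * nf]
  if (length(frames) < 50) abort("too few frames for the fit (< 50)")
  model <- traj$model
  seg <- model$beads$segment
  keep_bond <- rep(TRUE, nrow(model$bonds))
  if (!is.null(segment_label)) {
    keep_bond <- startsWith(seg[model$bonds$i], segment_label) &
      startsWith(seg[model$bonds$j], segment_label)
  }
  # bonds along each chain, in path order
  chains <- split(seq_len(nrow(model$bonds)), model$beads$chain[model$bonds$i])
  corr_sum <- numeric(max_lag); corr_n <- numeric(max_lag)
  for (f in frames) {
    p <- frame_positions(traj, f)
    for (bonds_ix in chains) {
      bx <- bonds_ix[keep_bond[bonds_ix]]
      if (length(bx) < 2) next
      tv <- p[model$bonds$j[bx], , drop = FALSE] -
        p[model$bonds$i[bx], , drop = FALSE]
      tv <- tv / sqrt(rowSums(tv^2))
      nb <- nrow(tv)
      for (lag in seq_len(min(max_lag, nb - 1))) {
        dots <- rowSums(tv[1:(nb - lag), , drop = FALSE] *
                          tv[(1 + lag):nb, , drop = FALSE])
        corr_sum[lag] <- corr_sum[lag] + sum(dots)
        corr_n[lag] <- corr_n[lag] + length(dots)
      }
    }
  }
  corr <- corr_sum / pmax(corr_n, 1)
  lags <- which(corr_n > 0 & corr > 0)
  if (length(lags) < 2 || corr[1] > 1 - 1e-4) {
    return(structure(Inf, flag = "ge_contour"))
  }
  fit <- lm(log(corr[lags]) ~ 0 + lags)
  slope <- coef(fit)[1]
  if (slope >= -1e-8) return(structure(Inf, flag = "ge_contour"))
  unname(-model$bond_length / slope)
}

#' Diameter of the disk with a given area
#'
#' `2 sqrt(area / pi)`: the equivalent-disk diameter used to express AFM
#' footprint areas as dot sizes (587 nm^2 is a 27.3 nm disk, 246 nm^2 a
#' 17.7 nm disk).
#'
#' @param area Area (nm^2), >= 0.
#' @return Diameter in nm.
#' @export
equivalent_disk_diameter <- function(area) {
  if (any(area < 0)) abort("`area` must be >= 0")
  2 * sqrt(area / pi)
}
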