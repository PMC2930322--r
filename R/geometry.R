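# Construction of coarse-grained subunit models and the substrate lattice.
#
# Conventions: all lengths in nm, energies in kcal/mol. The substrate plane is
# z = 0 and "vertical distance" means the +z coordinate. One bead represents
# 1 nm of dimer contour (default) and carries the residues of both strands of
# the coiled coil over that nm (~18 residues).

#' Build a coarse-grained IF dimer
#'
#' Constructs a straight bead-chain model of an intermediate-filament dimer:
#' two alpha-helical coiled-coil segments joined by the short flexible L12
#' linker. The chain is laid out along the x axis starting at the origin.
#' Beads are labelled `COIL1`, `LINKER` or `COIL2` by position; bending
#' joints centred on (or bordering) the linker are classed `HINGE`, all
#' others `COIL`. Coil beads carry one negative elementary charge by default
#' (the coiled-coil segments are negatively charged at assembly pH).
#'
#' @param bond_length Bead spacing along the contour (nm).
#' @param coil1_length,linker_length,coil2_length Segment lengths (nm). The
#'   defaults 22 + 3 + 25 give the canonical 50 nm dimer contour.
#' @param bead_radius Bead radius (nm); the dimer is ~2 nm wide.
#' @param residues_per_bead Number of amino-acid residues represented by one
#'   bead; used to scale per-residue adhesion and pull forces.
#' @param coil_charge Charge (e) on each coil bead; linker beads are neutral.
#' @return An object of class `ifp_model` with elements `beads` (tibble with
#'   `x`, `y`, `z`, `radius`, `residues_per_bead`, `charge`, `segment`,
#'   `chain`), `bonds`, `joints`, `crosslinks` (tibbles of 1-based bead
#'   indices), `kind`, `bond_length` and `contour_length_per_dimer`.
#' @examples
#' d <- build_dimer()
#' nrow(d$beads)            # 51 beads on the 50 nm contour
#' end_to_end_length(d)     # 50 nm when straight
#' @export
build_dimer <- function(bond_length = 1,
                        coil1_length = 22,
                        linker_length = 3,
                        coil2_length = 25,
                        bead_radius = 1,
                        residues_per_bead = 18,
                        coil_charge = -1) {
  stopifnot_scalar(bond_length, "bond_length", positive = TRUE)
  for (nm in c("coil1_length", "linker_length", "coil2_length")) {
    v <- get(nm)
    stopifnot_scalar(v, nm, nonneg = TRUE)
  }
  if (coil1_length <= 0 || coil2_length <= 0) {
    abort("coil segment lengths must be > 0")
  }
  total <- coil1_length + linker_length + coil2_length
  if (bond_length > max(coil1_length, coil2_length)) {
    abort("`bond_length` exceeds a segment length")
  }
  n <- round(total / bond_length) + 1L
  x <- (seq_len(n) - 1) * bond_length
  c1 <- coil1_length
  c2 <- coil1_length + linker_length
  segment <- ifelse(x < c1 | (linker_length == 0 & x <= c1), "COIL1",
                    ifelse(x > c2, "COIL2",
                           ifelse(x > c1 & x < c2, "LINKER",
                                  ifelse(x <= c1, "COIL1", "COIL2"))))
  beads <- tibble(
    x = x, y = 0, z = 0,
    radius = bead_radius,
    residues_per_bead = residues_per_bead,
    charge = ifelse(segment == "LINKER", 0, coil_charge),
    segment = segment,
    chain = 1L
  )
  bonds <- tibble(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L,
                  b0 = bond_length)
  ctr <- 2:(n - 1L)
  hinge <- x[ctr] >= c1 & x[ctr] <= c2 & linker_length > 0
  joints <- tibble(i = ctr - 1L, j = ctr, k = ctr + 1L,
                   class = ifelse(hinge, "HINGE", "COIL"))
  structure(list(
    beads = beads, bonds = bonds, joints = joints,
    crosslinks = tibble(i = integer(), j = integer(), b0 = numeric()),
    kind = "dimer", bond_length = bond_length,
    contour_length_per_dimer = total
  ), class = "ifp_model")
}

#' Build a single free coil
#'
#' A one-segment bead chain (no linker, no charges by default) used for
#' persistence-length recovery experiments and freely-jointed-chain controls.
#'
#' @param length Contour length (nm).
#' @param bond_length Bead spacing (nm).
#' @inheritParams build_dimer
#' @return An `ifp_model` of kind `"dimer"` with a single `COIL1` segment.
#' @export
build_coil <- function(length = 25, bond_length = 1, bead_radius = 1,
                       residues_per_bead = 18, coil_charge = 0) {
  m <- build_dimer(bond_length = bond_length, coil1_length = length / 2,
                   linker_length = 0, coil2_length = length / 2,
                   bead_radius = bead_radius,
                   residues_per_bead = residues_per_bead,
                   coil_charge = coil_charge)
  m$beads$segment <- "COIL1"
  m$joints$class <- "COIL"
  m
}

#' Build a coarse-grained IF tetramer
#'
#' Places two copies of a dimer in the antiparallel, half-staggered A11
#' arrangement: the second dimer runs in the opposite direction, shifted
#' axially by `stagger` and laterally by `lateral_gap`. Soft harmonic
#' crosslinks join facing beads in the overlap region, standing in for the
#' inter-dimer cohesion without modelling head-domain chemistry. With the
#' default 25 nm stagger two 50 nm dimers give a 75 nm rod.
#'
#' @param dimer_template An `ifp_model` from [build_dimer()].
#' @param stagger Axial offset between the two dimers (nm).
#' @param lateral_gap Distance between the two dimer axes (nm).
#' @return An `ifp_model` of kind `"tetramer"`; `chain` is 1 or 2.
#' @examples
#' t <- build_tetramer()
#' end_to_end_length(t)   # 75 nm straight-built
#' @export
build_tetramer <- function(dimer_template = build_dimer(), stagger = 25,
                           lateral_gap = 2) {
  stopifnot_scalar(stagger, "stagger", positive = TRUE)
  stopifnot_scalar(lateral_gap, "lateral_gap", positive = TRUE)
  L <- dimer_template$contour_length_per_dimer
  if (stagger >= L) abort("`stagger` >= dimer length leaves no overlap")
  a <- dimer_template
  b <- dimer_template
  # antiparallel: reverse orientation of dimer B, then shift by stagger
  b$beads$x <- (L + stagger) - b$beads$x
  b$beads$y <- b$beads$y + lateral_gap
  b$beads$chain <- 2L
  n <- nrow(a$beads)
  off <- function(tb) {
    tb$i <- tb$i + n; tb$j <- tb$j + n
    if ("k" %in% names(tb)) tb$k <- tb$k + n
    tb
  }
  beads <- bind_rows(a$beads, b$beads)
  bonds <- bind_rows(a$bonds, off(b$bonds))
  joints <- bind_rows(a$joints, off(b$joints))
  # crosslink facing beads in the axial overlap [stagger, L]
  ia <- which(a$beads$x >= stagger - 1e-9 & a$beads$x <= L + 1e-9)
  xlinks <- purrr::map_dfr(ia, function(i) {
    xb <- a$beads$x[i]
    jb <- which(abs(b$beads$x - xb) < 1e-9)
    if (length(jb) != 1L) return(NULL)
    tibble(i = i, j = jb + n, b0 = lateral_gap)
  })
  structure(list(
    beads = beads, bonds = bonds, joints = joints, crosslinks = xlinks,
    kind = "tetramer", bond_length = dimer_template$bond_length,
    contour_length_per_dimer = L
  ), class = "ifp_model")
}

#' Build the hexagonal substrate lattice
#'
#' Adhesion beads are placed at the nodes of a triangular ("hexagonal")
#' lattice in the z = 0 plane with nearest-neighbour distance `spacing`
#' (0.98 nm for the silica-derived substrate). The lattice is centred on the
#' origin and spans `width` in x and `depth` in y.
#'
#' @param spacing Nearest-neighbour distance (nm).
#' @param width,depth Extent of the lattice (nm).
#' @param lj An [lj_params()] object: per-pair well depth and the distance of
#'   zero force for chain-bead/substrate-bead interactions.
#' @return An object of class `ifp_substrate` with `positions` (tibble),
#'   `spacing`, `lj`, `extent`, and the anchor `x0`, `y0` of the periodic
#'   cell (used by the simulation engine).
#' @examples
#' s <- build_substrate(width = 20, depth = 20)
#' s$spacing
#' @export
build_substrate <- function(spacing = 0.98, width = 60, depth = 20,
                            lj = lj_params(0.1177, 0.49)) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  stopifnot_scalar(width, "width", positive = TRUE)
  stopifnot_scalar(depth, "depth", positive = TRUE)
  x0 <- -width / 2; y0 <- -depth / 2
  rowh <- spacing * sqrt(3) / 2
  nrow_ <- floor(depth / rowh) + 1L
  ncol_ <- floor(width / spacing) + 1L
  j <- rep(seq_len(nrow_) - 1L, each = ncol_)
  i <- rep(seq_len(ncol_) - 1L, times = nrow_)
  x <- x0 + i * spacing + (j %% 2L) * spacing / 2
  y <- y0 + j * rowh
  keep <- x <= x0 + width + 1e-9
  structure(list(
    positions = tibble(x = x[keep], y = y[keep], z = 0),
    spacing = spacing, lj = lj, extent = c(width = width, depth = depth),
    x0 = x0, y0 = y0
  ), class = "ifp_substrate")
}

#' @export
print.ifp_model <- function(x, ...) {
  cat(sprintf("<ifp_model: %s, %d beads, bond %.3g nm, contour %g nm/dimer>\n",
              x$kind, nrow(x$beads), x$bond_length,
              x$contour_length_per_dimer))
  invisible(x)
}

#' @export
print.ifp_substrate <- function(x, ...) {
  cat(sprintf(
    "<ifp_substrate: %d beads, spacing %.3g nm, %g x %g nm, eps %.4g, r_min %.3g>\n",
    nrow(x$positions), x$spacing, x$extent[1], x$extent[2],
    x$lj$well_depth, x$lj$r_min))
  invisible(x)
}

#' Tidy a subunit model into its bead table
#'
#' @param x An `ifp_model`.
#' @param ... Unused.
#' @return The bead tibble with a `bead` index column.
#' @export
tidy.ifp_model <- function(x, ...) {
  mutate(x$beads, bead = dplyr::row_number(), .before = 1)
}

#' Terminal bead indices of each chain in a model
#'
#' @param model An `ifp_model`.
#' @return A tibble with `chain`, `first`, `last` bead indices.
#' @export
chain_termini <- function(model) {
  ch <- model$beads$chain
  purrr::map_dfr(unique(ch), function(c0) {
    idx <- which(ch == c0)
    tibble(chain = c0, first = idx[1], last = idx[length(idx)])
  })
}
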