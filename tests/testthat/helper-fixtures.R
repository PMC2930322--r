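# Shared fixtures, all built in code at test time.

# a model with a single bead (radius 1), for area/SASA identities
single_bead_model <- function(radius = 1) {
  m <- build_coil(2, 1, bead_radius = radius)
  m$beads <- m$beads[1, ]
  m$bonds <- m$bonds[0, ]
  m$joints <- m$joints[0, ]
  m
}

# two-bead model at a given separation
two_bead_model <- function(d, radius = 1) {
  m <- build_coil(2, 1, bead_radius = radius)
  m$beads <- m$beads[1:2, ]
  m$beads$x <- c(0, d)
  m$bonds <- m$bonds[0, ]
  m$joints <- m$joints[0, ]
  m
}

# three-bead chain with one joint at a right angle, known bending constant
right_angle_chain <- function() {
  m <- build_coil(2, 1)
  m$beads$x <- c(0, 1, 1)
  m$beads$y <- c(0, 0, 1)
  m
}

# perfect hairpin: two 25 nm arms a small gap apart
hairpin_dimer <- function(gap = 2) {
  m <- build_dimer()
  m$beads$x <- c(seq(0, 25, 1), seq(24, 0, -1))
  m$beads$y <- c(rep(0, 26), rep(gap, 25))
  m
}

# memoised mid-size vimentin scene reused across AFM tests
fixture_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene("vimentin_NaCl", n_subunits = 200,
                               image_size = 1400, seed = 11)
    }
    cache
  }
})

# random rigid motion of a coordinate set
random_rigid <- function(p, seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    sweep(p %*% t(R), 2, rnorm(3, 0, 5), `+`)
  })
}

# 1-px erosion of a pixel-index mask within an nr x nc image
erode_mask <- function(idx, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  keep <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    keep <- keep & ifplast:::shift_matrix(m, di, dj, fill = FALSE)
  }
  which(keep)
}

dilate_mask <- function(idx, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  which(ifplast:::dilate1(m))
}
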