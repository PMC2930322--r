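# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Shift a matrix by (di, dj) pixels, padding with `fill`.
shift_matrix <- function(m, di, dj, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); cj <- seq_len(nc)
  src_i <- ri - di; src_j <- cj - dj
  ok_i <- src_i >= 1 & src_i <= nr
  ok_j <- src_j >= 1 & src_j <= nc
  out[ri[ok_i], cj[ok_j]] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

# 3x3 mean filter with edge renormalisation (same weights as a box blur).
mean_filter3 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  ones <- matrix(1, nrow(m), ncol(m))
  for (di in -1:1) {
    for (dj in -1:1) {
      acc <- acc + shift_matrix(m, di, dj, fill = 0)
      cnt <- cnt + shift_matrix(ones, di, dj, fill = 0)
    }
  }
  acc / cnt
}

# Binary dilation of a logical matrix by a 1-pixel 8-neighbourhood.
dilate1 <- function(mask) {
  out <- mask
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      out <- out | shift_matrix(mask, di, dj, fill = FALSE)
    }
  }
  out
}

# Coordinates of model beads as an N x 3 matrix.
bead_coords <- function(model) {
  as.matrix(model$beads[, c("x", "y", "z")])
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
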