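# Synthetic AFM scene generator: renders height maps of dried IF subunits
# (dots and curly threads) and filaments whose object statistics emulate the
# measured populations, with full ground truth for pipeline validation.

#' AFM scene presets
#'
#' One row per imaging condition, with the measured population statistics:
#' mean/sd of per-object peak height (nm), mean footprint area (nm^2; the
#' areas are exponentially distributed), the dot fraction (the remainder are
#' curly threads), thread geometry, and filament density/height. The four
#' conditions are vimentin in NaCl (0.31 +/- 0.07 nm, 570 nm^2, filaments
#' present), keratin K5/K14 in NaCl (0.62 +/- 0.07 nm, 909 nm^2, longer and
#' curlier threads), K5/K14 glutaraldehyde-fixed (0.66 +/- 0.07 nm, 587
#' nm^2, mainly dots) and K5/K14 in CaCl2 (0.51 +/- 0.06 nm, 246 nm^2,
#' mainly dots). Filaments image as flat tapes of height 2.5 +/- 0.8 nm.
#'
#' @return A tibble of presets.
#' @export
afm_presets <- function() {
  tibble(
    name = c("vimentin_NaCl", "K5K14_NaCl", "K5K14_glutaraldehyde",
             "K5K14_CaCl2"),
    dot_fraction = c(0.5, 0.4, 0.9, 0.9),
    mean_height = c(0.31, 0.62, 0.66, 0.51),
    sd_height = c(0.07, 0.07, 0.07, 0.06),
    mean_area = c(570, 909, 587, 246),
    thread_width = 6,
    thread_step = 2,
    thread_persistence = 50,
    filament_density = c(0.5, 0, 0, 0),
    filament_height = 2.5,
    filament_sd = 0.8,
    filament_width = 12
  )
}

get_preset <- function(preset) {
  if (is.character(preset)) {
    tb <- afm_presets()
    row <- tb[tb$name == preset, ]
    if (nrow(row) != 1) abort(sprintf("unknown preset '%s'", preset))
    return(row)
  }
  as_tibble(preset)
}

# spherical-cap profile: height h, base radius a, evaluated at radius r
cap_profile <- function(r, a, h) {
  R <- (a^2 + h^2) / (2 * h)
  z <- sqrt(pmax(R^2 - r^2, 0)) - (R - h)
  ifelse(r < a, pmax(z, 0), 0)
}

clamp_range <- function(lo, hi, n) {
  lo <- max(1L, lo); hi <- min(n, hi)
  if (lo > hi) integer() else lo:hi
}

# n-fold 8-neighbourhood binary dilation (small masks only)
dilate_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate1(mask)
  mask
}

#' Generate a synthetic AFM height map
#'
#' Places `n_subunits` objects at random non-overlapping positions (rejection
#' sampling with a separation margin): dots are spherical caps whose true
#' footprint areas are drawn from an exponential distribution with the
#' preset mean, threads are discrete 2D worm-like paths (given step and
#' planar persistence length) of the preset width with a cap cross-profile.
#' Per-object peak heights are normal with the preset mean/sd, truncated at
#' zero; each rendered object is rescaled so its maximum equals its drawn
#' height exactly. Filaments (if the preset has a nonzero density) are long
#' straight tapes crossing the image. Every placed object is recorded in
#' `ground_truth` with its footprint mask, so the support of the clean map
#' equals the union of the recorded masks.
#'
#' @param preset Preset name or a one-row preset tibble (see [afm_presets()]).
#' @param n_subunits Number of subunit objects.
#' @param image_size Image side (nm).
#' @param pixel_size Pixel size (nm); the 1 nm default resolves the 6 nm
#'   thread width and sub-nm peak sampling.
#' @param seed Integer seed; scenes are reproducible bit-for-bit.
#' @param n_contacting Number of extra dots deliberately placed touching a
#'   filament (for validating the contact-exclusion rule); requires
#'   filaments in the scene.
#' @param margin_px Separation margin between object footprints (pixels).
#' @return An object of class `ifp_afm_image`: `heights` (matrix, nm; rows
#'   index y), `pixel_size`, `preset`, `seed`, `ground_truth` (tibble with
#'   `id`, `class`, `area_true`, `height_true`, `cx`, `cy`,
#'   `placed_contacting`), `masks` (list of pixel-index vectors per object),
#'   `filament_mask`.
#' @export
generate_scene <- function(preset = "vimentin_NaCl", n_subunits = 500,
                           image_size = 2000, pixel_size = 1, seed = 1,
                           n_contacting = 0, margin_px = 3) {
  if (pixel_size > 4) abort("`pixel_size` must be <= 4 nm")
  pr <- get_preset(preset)
  npx <- round(image_size / pixel_size)
  with_local_seed(seed, {
    img <- matrix(0, npx, npx)
    occ <- matrix(FALSE, npx, npx)       # all footprints + margin
    fil_foot <- matrix(FALSE, npx, npx)  # filament footprint
    truth <- list(); masks <- list(); id <- 0L

    n_fil <- round(pr$filament_density * (image_size / 1000)^2)
    for (f in seq_len(n_fil)) {
      h <- max(0.5, rnorm(1, pr$filament_height, pr$filament_sd))
      ang <- runif(1, 0, pi)
      off <- runif(1, -image_size / 4, image_size / 4)
      nx_ <- cos(ang + pi / 2); ny_ <- sin(ang + pi / 2)
      px <- (col(img) - 0.5) * pixel_size - image_size / 2
      py <- (row(img) - 0.5) * pixel_size - image_size / 2
      dist <- abs((px - off * nx_) * nx_ + (py - off * ny_) * ny_)
      patch <- cap_profile(dist, pr$filament_width / 2, h)
      if (max(patch) <= 0) next
      patch <- patch * (h / max(patch))
      sel <- patch > 0
      img[sel] <- pmax(img[sel], patch[sel])
      idx <- which(sel)
      id <- id + 1L
      truth[[id]] <- tibble(id = id, class = "filament",
                            area_true = length(idx) * pixel_size^2,
                            height_true = h, cx = NA_real_, cy = NA_real_,
                            placed_contacting = FALSE)
      masks[[id]] <- idx
      fil_foot <- fil_foot | sel
      occ <- occ | dilate_n(sel, margin_px)
    }
    fil_gap2 <- dilate_n(fil_foot, 2)       # footprint + 2-px ring
    fil_gap3 <- dilate1(fil_gap2)           # footprint + 3-px ring
    fil_margin <- dilate_n(fil_foot, margin_px)

    commit <- function(ri, ci, patch, klass, A, h, contacting) {
      foot <- patch > 0
      img[ri, ci] <<- pmax(img[ri, ci], patch)
      lin <- which(foot)
      gidx <- (rep(ci, each = length(ri))[lin] - 1L) * npx +
        rep(ri, times = length(ci))[lin]
      id <<- id + 1L
      truth[[id]] <<- tibble(
        id = id, class = klass, area_true = A, height_true = h,
        cx = (mean(((gidx - 1L) %/% npx) + 1L) - 0.5) * pixel_size,
        cy = (mean(((gidx - 1L) %% npx) + 1L) - 0.5) * pixel_size,
        placed_contacting = contacting)
      masks[[id]] <<- gidx
      # grow occupancy locally around the new footprint
      r0 <- clamp_range(min(ri) - margin_px, max(ri) + margin_px, npx)
      c0 <- clamp_range(min(ci) - margin_px, max(ci) + margin_px, npx)
      loc <- matrix(FALSE, length(r0), length(c0))
      loc[cbind(match(((gidx - 1L) %% npx) + 1L, r0),
                match(((gidx - 1L) %/% npx) + 1L, c0))] <- TRUE
      occ[r0, c0] <<- occ[r0, c0] | dilate_n(loc, margin_px)
      invisible(TRUE)
    }

    draw_object <- function(klass) {
      A <- max(rexp(1, 1 / pr$mean_area), 2 * pixel_size^2)
      h <- 0
      while (h <= 0) h <- rnorm(1, pr$mean_height, pr$sd_height)
      obj <- if (klass == "dot") render_dot(A, h, pixel_size)
      else render_thread(A, h, pr, pixel_size)
      list(A = A, h = h, klass = klass, patch = obj$patch)
    }

    place_free <- function(ob) {
      # the object's size and height were drawn up front; only its position
      # (and, for threads, the path realisation) is re-sampled on rejection,
      # so placement does not bias the area distribution
      klass <- ob$klass
      for (attempt in 1:400) {
        if (attempt > 1 && klass == "thread") {
          ob$patch <- render_thread(ob$A, ob$h, pr, pixel_size)$patch
        }
        win <- dim(ob$patch)
        if (win[1] + 2 >= npx || win[2] + 2 >= npx) next
        r0 <- sample.int(npx - win[1] - 1L, 1) + 1L
        c0 <- sample.int(npx - win[2] - 1L, 1) + 1L
        ri <- r0:(r0 + win[1] - 1L); ci <- c0:(c0 + win[2] - 1L)
        fp <- dilate_n(ob$patch > 0, margin_px)
        if (any(occ[ri, ci] & fp)) next
        return(commit(ri, ci, ob$patch, klass, ob$A, ob$h, FALSE))
      }
      abort(sprintf("cannot place a %s without overlap; reduce n_subunits", klass))
    }

    place_contacting <- function() {
      fil_idx <- which(fil_foot)
      if (length(fil_idx) == 0) abort("no filaments to contact")
      for (attempt in 1:500) {
        ob <- draw_object("dot")
        win <- dim(ob$patch)
        pxl <- fil_idx[sample.int(length(fil_idx), 1)]
        fr <- ((pxl - 1L) %% npx) + 1L
        fc <- ((pxl - 1L) %/% npx) + 1L
        d <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))[[sample.int(4, 1)]]
        # walk to the footprint boundary along d
        step <- 0L; r2 <- fr; c2 <- fc
        ok <- TRUE
        repeat {
          step <- step + 1L
          r2 <- fr + d[1] * step; c2 <- fc + d[2] * step
          if (r2 < 2 || c2 < 2 || r2 > npx - 1 || c2 > npx - 1) { ok <- FALSE; break }
          if (!fil_foot[r2, c2]) break
          if (step > 80) { ok <- FALSE; break }
        }
        if (!ok) next
        # slide the window outward from the boundary until the footprint
        # sits exactly in the 3-px contact band: close enough to count as a
        # filament contact, far enough that 8-connected labelling keeps the
        # dot a separate object even after threshold smear widens both
        # footprints by a pixel
        for (shift in 0:6) {
          r0 <- if (d[1] > 0) r2 + shift else if (d[1] < 0) r2 - win[1] + 1L - shift else r2 - floor(win[1] / 2)
          c0 <- if (d[2] > 0) c2 + shift else if (d[2] < 0) c2 - win[2] + 1L - shift else c2 - floor(win[2] / 2)
          if (r0 < 2 || c0 < 2 || r0 + win[1] > npx || c0 + win[2] > npx) next
          ri <- r0:(r0 + win[1] - 1L); ci <- c0:(c0 + win[2] - 1L)
          foot <- ob$patch > 0
          if (any(fil_gap2[ri, ci] & foot)) next          # gap >= 3 px
          if (!any(fil_gap3[ri, ci] & foot)) next         # gap == 3 px
          other <- occ[ri, ci] & !fil_margin[ri, ci]
          if (any(other & dilate_n(foot, margin_px))) next
          return(commit(ri, ci, ob$patch, "dot", ob$A, ob$h, TRUE))
        }
      }
      abort("cannot place a contacting dot")
    }

    # draw the whole population first, then place largest-first: big objects
    # get the emptiest canvas, which keeps rejection sampling feasible at
    # high fill without touching the drawn area distribution
    classes <- ifelse(runif(n_subunits) < pr$dot_fraction, "dot", "thread")
    objects <- lapply(classes, draw_object)
    for (ob in objects[order(-vapply(objects, function(o) o$A, numeric(1)))]) {
      place_free(ob)
    }
    for (i in seq_len(n_contacting)) place_contacting()

    structure(list(heights = img, pixel_size = pixel_size,
                   preset = pr$name, seed = seed,
                   ground_truth = if (id > 0) bind_rows(truth) else
                     tibble(id = integer(), class = character(),
                            area_true = numeric(), height_true = numeric(),
                            cx = numeric(), cy = numeric(),
                            placed_contacting = logical()),
                   masks = masks,
                   filament_mask = which(fil_foot),
                   provenance = list(tip_radius = 0, noise_sigma = 0)),
              class = "ifp_afm_image")
  })
}

# rendered dot patch: spherical cap with base radius from the true area
render_dot <- function(area, h, pixel_size) {
  a <- sqrt(area / pi)
  wpx <- ceiling(a / pixel_size) + 1L
  n <- 2L * wpx + 1L
  ctr <- (wpx + runif(2)) * pixel_size  # sub-pixel jitter of the centre
  gx <- (col(matrix(0, n, n)) - 0.5) * pixel_size
  gy <- (row(matrix(0, n, n)) - 0.5) * pixel_size
  r <- sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2)
  patch <- cap_profile(r, a, h)
  if (max(patch) <= 0) {  # sub-pixel object: peak on one pixel
    patch[wpx + 1L, wpx + 1L] <- h
  }
  list(patch = patch * (h / max(patch)))
}

# rendered thread patch: 2D worm-like centreline, cap cross-profile
render_thread <- function(area, h, pr, pixel_size) {
  w <- pr$thread_width
  len <- max(area / w, pr$thread_step)
  nstep <- max(2L, ceiling(len / pr$thread_step))
  dth <- rnorm(nstep, 0, sqrt(pr$thread_step / pr$thread_persistence))
  th <- runif(1, 0, 2 * pi) + cumsum(dth)
  xs <- cumsum(c(0, pr$thread_step * cos(th)))
  ys <- cumsum(c(0, pr$thread_step * sin(th)))
  seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seglen))
  si <- seq(0, s[length(s)], by = pixel_size * 0.7)
  cx <- stats::approx(s, xs, si)$y
  cy <- stats::approx(s, ys, si)$y
  half <- w / 2
  pad <- half + 2 * pixel_size
  x0 <- min(cx) - pad; y0 <- min(cy) - pad
  nxw <- ceiling((max(cx) - x0 + pad) / pixel_size)
  nyw <- ceiling((max(cy) - y0 + pad) / pixel_size)
  dist <- matrix(Inf, nyw, nxw)
  rad_px <- ceiling(pad / pixel_size)
  for (p in seq_along(cx)) {
    ic <- floor((cx[p] - x0) / pixel_size) + 1L
    ir <- floor((cy[p] - y0) / pixel_size) + 1L
    rr <- clamp_range(ir - rad_px, ir + rad_px, nyw)
    cc <- clamp_range(ic - rad_px, ic + rad_px, nxw)
    gx <- x0 + (cc - 0.5) * pixel_size
    gy <- y0 + (rr - 0.5) * pixel_size
    d <- sqrt(outer((gy - cy[p])^2, (gx - cx[p])^2, `+`))
    dist[rr, cc] <- pmin(dist[rr, cc], d)
  }
  patch <- cap_profile(dist, half, h)
  if (max(patch) <= 0) patch[ceiling(nyw / 2), ceiling(nxw / 2)] <- h
  list(patch = patch * (h / max(patch)))
}

#' Apply tip dilation to a height map
#'
#' Models the finite AFM tip as grayscale morphological dilation by a
#' spherical-cap structuring element of the given radius: each output pixel
#' is the maximum over the neighbourhood of the input plus the (negative)
#' cap offset. The output is everywhere >= the input; a zero radius is the
#' identity.
#'
#' @param image An `ifp_afm_image` (or bare matrix).
#' @param tip_radius Tip radius (nm), >= 0.
#' @return The dilated image, same class as the input.
#' @export
render_tip_dilation <- function(image, tip_radius) {
  if (tip_radius < 0) abort("`tip_radius` must be >= 0")
  m <- if (inherits(image, "ifp_afm_image")) image$heights else image
  px <- if (inherits(image, "ifp_afm_image")) image$pixel_size else 1
  if (tip_radius > 0) {
    kpx <- floor(tip_radius / px)
    out <- m
    for (di in -kpx:kpx) {
      for (dj in -kpx:kpx) {
        if (di == 0 && dj == 0) next
        d <- sqrt(di^2 + dj^2) * px
        if (d > tip_radius) next
        se <- sqrt(tip_radius^2 - d^2) - tip_radius
        out <- pmax(out, shift_matrix(m, di, dj, fill = -Inf) + se)
      }
    }
    m <- out
  }
  if (inherits(image, "ifp_afm_image")) {
    image$heights <- m
    image$provenance$tip_radius <- tip_radius
    image
  } else m
}

#' Add instrument noise to a height map
#'
#' Adds zero-mean Gaussian height noise of the given standard deviation, a
#' stand-in for instrument noise.
#'
#' @param image An `ifp_afm_image` (or bare matrix).
#' @param sigma Noise sd (nm), >= 0.
#' @param seed Integer seed for reproducibility (`NULL` uses the current RNG
#'   state).
#' @return The noisy image, same class as the input.
#' @export
add_noise <- function(image, sigma = 0.03, seed = NULL) {
  if (sigma < 0) abort("`sigma` must be >= 0")
  m <- if (inherits(image, "ifp_afm_image")) image$heights else image
  if (sigma > 0) {
    noise <- with_local_seed(seed, matrix(rnorm(length(m), 0, sigma),
                                          nrow(m), ncol(m)))
    m <- m + noise
  }
  if (inherits(image, "ifp_afm_image")) {
    image$heights <- m
    image$provenance$noise_sigma <- sigma
    image
  } else m
}

#' @export
print.ifp_afm_image <- function(x, ...) {
  cat(sprintf("<ifp_afm_image: %s, %d x %d px at %.3g nm, seed %s, %d objects>\n",
              x$preset, nrow(x$heights), ncol(x$heights), x$pixel_size,
              x$seed, nrow(x$ground_truth)))
  invisible(x)
}

#' Plot an AFM height map
#'
#' @param object An `ifp_afm_image`.
#' @param ... Unused.
#' @return A ggplot raster of the height field.
#' @export
autoplot.ifp_afm_image <- function(object, ...) {
  df <- expand.grid(
    x = (seq_len(ncol(object$heights)) - 0.5) * object$pixel_size,
    y = (seq_len(nrow(object$heights)) - 0.5) * object$pixel_size
  )
  df$height <- as.vector(t(object$heights))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("synthetic AFM: %s", object$preset))
}
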