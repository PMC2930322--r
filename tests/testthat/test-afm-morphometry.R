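test_that("background flattening removes planes exactly and recentres", {
  flat <- matrix(0.5, 60, 80)
  out <- flatten_background(flat)
  expect_lt(max(abs(out)), 1e-9)
  tilt <- outer(1:60, 1:80, function(i, j) 0.01 * i - 0.007 * j + 2)
  rec <- flatten_background(flat + tilt)
  expect_lt(max(abs(rec)), 1e-6)
  withr::with_seed(3, noisy <- matrix(rnorm(4800, 0, 0.03), 60, 80) + tilt)
  out2 <- flatten_background(noisy)
  expect_lt(abs(median(out2)), 1e-9)
})

test_that("segmentation finds no objects in pure noise at a high threshold", {
  nz <- add_noise(matrix(0, 600, 600), 0.03, seed = 3)
  seg <- segment_objects(nz, k_sigma = 5)
  expect_equal(nrow(seg$records), 0)
})

test_that("well-separated synthetic dots are each found once", {
  m <- matrix(0, 400, 400)
  centres <- cbind(c(60, 60, 200, 330, 330), c(60, 300, 180, 80, 320))
  for (k in seq_len(nrow(centres))) {
    r2 <- outer((seq_len(400) - centres[k, 1])^2,
                (seq_len(400) - centres[k, 2])^2, `+`)
    m <- m + 0.4 * pmax(1 - r2 / 100, 0)
  }
  seg <- segment_objects(add_noise(m, 0.02, seed = 4), k_sigma = 3)
  rec <- seg$records
  expect_equal(nrow(rec), 5)
  expect_true(all(!rec$touches_border))
  expect_true(all(rec$class_guess == "dot"))
  expect_equal(sort(rec$max_height), rep(0.4, 5), tolerance = 0.12)
})

test_that("measured footprints match ground-truth masks within one pixel ring", {
  # noiseless, no tip; the clean image is flat by construction, so the
  # robust threshold is zero and segmentation sees the exact support
  img <- fixture_scene()
  seg <- segment_objects(img, denoise = FALSE, min_area_px = 1)
  lab <- seg$labels
  nr <- nrow(lab); nc <- ncol(lab)
  tr <- img$ground_truth
  ok_sub <- which(tr$class != "filament")
  for (i in ok_sub) {
    msk <- img$masks[[i]]
    ls <- setdiff(unique(lab[msk]), 0L)
    expect_length(ls, 1)
    measured <- which(lab == ls)
    expect_true(all(erode_mask(msk, nr, nc) %in% measured))
    expect_true(all(measured %in% dilate_mask(msk, nr, nc)))
  }
})

test_that("filament contacts are excluded from the statistics", {
  # no filaments: the filter is the identity
  img0 <- generate_scene("K5K14_CaCl2", n_subunits = 25, image_size = 700,
                         seed = 13)
  seg0 <- segment_objects(flatten_background(img0))
  expect_identical(exclude_filament_contacts(seg0)$records, seg0$records)
  # known number of contacting placements is flagged and removed
  img <- generate_scene("vimentin_NaCl", n_subunits = 40, image_size = 1500,
                        seed = 21, n_contacting = 3)
  img <- add_noise(img, 0.02, seed = 22)
  seg <- measure_afm_image(img)
  expect_equal(sum(seg$records$contacts_filament), 3)
  kept <- summarize_objects(seg)
  all_int <- seg$records[!seg$records$touches_border &
                           seg$records$class_guess != "filament", ]
  expect_equal(kept$n, nrow(all_int) - 3)
})

test_that("population summary follows the documented conventions", {
  rec <- tibble::tibble(
    label = 1:3, area = c(100, 200, 300), max_height = c(0.2, 0.3, 0.4),
    cx = 0, cy = 0, n_px = c(100L, 200L, 300L), touches_border = FALSE,
    elongation = 1, class_guess = "dot", contacts_filament = FALSE)
  sm <- summarize_objects(rec)
  expect_equal(sm$mean_height, 0.3)
  expect_equal(sm$sd_height, 0.1)
  expect_equal(sm$mean_area, 200)
  expect_equal(sm$n, 3)
  one <- summarize_objects(rec[1, ])
  expect_equal(one$sd_height, 0)
  expect_true(one$single)
  expect_error(summarize_objects(rec[0, ]), "no analysable")
  # adding one clean object increments n by exactly one
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec[1, ], label = 4L))
  expect_equal(summarize_objects(rec2)$n, sm$n + 1)
})

test_that("area distribution is normalised and fits exponential samples", {
  withr::with_seed(31, {
    rec <- tibble::tibble(
      label = 1:1000, area = rexp(1000, 1 / 570), max_height = 0.3,
      cx = 0, cy = 0, n_px = 10L, touches_border = FALSE, elongation = 1,
      class_guess = "dot", contacts_filament = FALSE)
  })
  ad <- area_probability_distribution(rec, bins = 40)
  expect_equal(sum(ad$table$probability), 1, tolerance = 1e-9)
  expect_equal(ad$n, 1000)
  # Kolmogorov-Smirnov distance to the fitted exponential under the
  # n = 1000 critical scale
  ks <- suppressWarnings(stats::ks.test(rec$area, "pexp",
                                        rate = 1 / ad$fitted_mean))
  expect_lt(unname(ks$statistic), 0.06)
  expect_error(area_probability_distribution(rec[1:10, ]), ">= 20")
})

test_that("keratin scenes occupy more area than vimentin scenes", {
  fit_mean <- function(preset) {
    img <- generate_scene(preset, n_subunits = 150, image_size = 1400,
                          seed = 17)
    img <- add_noise(render_tip_dilation(img, 3), 0.03, seed = 18)
    area_probability_distribution(measure_afm_image(img))$fitted_mean
  }
  expect_gt(fit_mean("K5K14_NaCl"), fit_mean("vimentin_NaCl"))
})
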