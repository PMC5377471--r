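# Tracer detection, interface extraction, and reworking metrics.

flat_image <- function(h = 60, w = 40, interface_row = 20, ps = 0.02,
                       tracers = NULL) {
  # water above interface_row, sediment below, optional tracer pixels
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 0.45; img[, , 2] <- 0.38; img[, , 3] <- 0.30
  for (ch in 1:3) {
    img[1:(interface_row - 1), , ch] <- c(0.02, 0.02, 0.10)[ch]
  }
  if (!is.null(tracers)) {
    h3 <- h * w
    lin <- (tracers[, 2] - 1) * h + tracers[, 1]
    img[lin] <- 1; img[lin + h3] <- 0; img[lin + 2 * h3] <- 0.8
  }
  profile_image(img, ps)
}

test_that("tracer mask equals the generated ground-truth set when noise is off", {
  g <- make_profile_image(species_archetype("gallery_diffuser"), 240, 420,
                          pixel_size = 0.025, seed = 31, n_particles = 1200,
                          matrix_noise_sd = 0)
  m <- detect_tracers(g$image)
  got <- which(m$mask, arr.ind = TRUE)
  want <- g$ground_truth$tracer_px
  expect_equal(sort(got[, 1] + nrow(m$mask) * got[, 2]),
               sort(want[, 1] + nrow(m$mask) * want[, 2]))
})

test_that("an all-black image yields an empty mask without error", {
  img <- profile_image(array(0, c(20, 20, 3)), 0.02)
  m <- detect_tracers(img)
  expect_equal(m$n_tracer_px, 0L)
})

test_that("isolated speckle is removed while clustered signal is kept", {
  g <- make_profile_image(species_archetype("u_tube"), 220, 380,
                          pixel_size = 0.025, seed = 13, n_particles = 900,
                          matrix_noise_sd = 0)
  noisy <- add_speckle_noise(g$image, frac = 0.05, seed = 14)
  m <- detect_tracers(noisy$image)
  h <- nrow(m$mask)
  got <- which(m$mask)
  want <- (g$ground_truth$tracer_px[, 2] - 1) * h + g$ground_truth$tracer_px[, 1]
  recovered <- mean(want %in% got)
  false_px <- sum(!got %in% want)
  expect_gte(recovered, 0.99)
  expect_lte(false_px / length(want), 0.01)
})

test_that("a flat interface is recovered exactly with zero SBR", {
  img <- flat_image(interface_row = 20)
  i <- detect_interface(img)
  expect_true(all(i$elevation == 20))
  expect_true(all(i$valid))
  expect_warning(met <- reworking_metrics(detect_tracers(img), i,
                                          img$pixel_size), "empty")
  expect_equal(met$SBR_cm, 0)
})

test_that("rough interface elevations match ground truth within one pixel", {
  for (seed in c(41, 42, 43)) {
    g <- make_profile_image(species_archetype("i_shaft"), 280, 420,
                            pixel_size = 0.02, seed = seed, n_particles = 700,
                            matrix_noise_sd = 0)
    i <- detect_interface(g$image)
    frac <- mean(abs(i$elevation - g$ground_truth$interface_elevation) <= 1)
    expect_gte(frac, 0.95)
  }
})

test_that("a single-column interface spike is removed by the median filter", {
  img <- flat_image(h = 60, w = 41, interface_row = 25)
  # carve a 1-px-wide water spike down to row 33 in column 21
  img$pixels[25:33, 21, 1] <- 0.02
  img$pixels[25:33, 21, 2] <- 0.02
  img$pixels[25:33, 21, 3] <- 0.10
  i <- detect_interface(img, median_window = 11)
  # brute-force running-median oracle on the raw first-hit profile
  raw <- rep(25L, 41); raw[21] <- 34L
  oracle <- vapply(seq_along(raw), function(j) {
    win <- raw[max(1, j - 5):min(41, j + 5)]
    median(win)
  }, 0)
  expect_equal(i$elevation[21], 25)
  expect_equal(max(abs(i$elevation - oracle)), 0)
})

test_that("a mostly signal-free image raises a degraded-image error", {
  img <- flat_image(h = 40, w = 30, interface_row = 10)
  img$pixels[, 1:20, ] <- 0.01      # 2/3 of columns all-dark
  expect_error(detect_interface(img), "degraded")
})

test_that("hand-computed depths give the expected summary statistics", {
  ps <- 0.1   # 0.1 cm/px so depths {0.1, 0.2, 0.9} cm sit 1, 2, 9 px deep
  img <- flat_image(h = 40, w = 30, interface_row = 10, ps = ps,
                    tracers = cbind(c(11, 12, 19), c(5, 10, 15)))
  met <- reworking_metrics(detect_tracers(img, filter_isolated = FALSE),
                           detect_interface(img), ps)
  expect_equal(met$L_med_cm, 0.2)
  expect_equal(met$L_mean_cm, 0.4)
  expect_equal(met$L_max_cm, 0.9)
})

test_that("metrics are translation invariant and scale covariant", {
  g <- make_profile_image(species_archetype("u_tube"), 200, 300,
                          pixel_size = 0.02, seed = 17, n_particles = 500,
                          matrix_noise_sd = 0)
  m <- detect_tracers(g$image); i <- detect_interface(g$image)
  base <- reworking_metrics(m, i, 0.02)
  # shift mask and interface together by 15 rows
  h <- nrow(m$mask)
  m2 <- structure(list(mask = rbind(matrix(FALSE, 15, ncol(m$mask)),
                                    m$mask[1:(h - 15), ]),
                       n_tracer_px = m$n_tracer_px), class = "tracer_mask")
  i2 <- structure(list(elevation = i$elevation + 15L, valid = i$valid,
                       luminance_threshold = i$luminance_threshold),
                  class = "interface_profile")
  shifted <- reworking_metrics(m2, i2, 0.02)
  expect_equal(shifted[2:5], base[2:5])
  # doubling the pixel size doubles every length-valued metric exactly
  doubled <- reworking_metrics(m, i, 0.04)
  expect_equal(doubled$L_med_cm, 2 * base$L_med_cm)
  expect_equal(doubled$L_mean_cm, 2 * base$L_mean_cm)
  expect_equal(doubled$L_max_cm, 2 * base$L_max_cm)
  expect_equal(doubled$SBR_cm, 2 * base$SBR_cm)
})

test_that("appending a deeper tracer pixel strictly increases L_max", {
  ps <- 0.05
  img <- flat_image(h = 60, w = 30, interface_row = 10, ps = ps,
                    tracers = cbind(c(12, 14, 16), c(5, 10, 15)))
  base <- reworking_metrics(detect_tracers(img, filter_isolated = FALSE),
                            detect_interface(img), ps)
  img2 <- flat_image(h = 60, w = 30, interface_row = 10, ps = ps,
                     tracers = cbind(c(12, 14, 16, 40), c(5, 10, 15, 20)))
  deeper <- reworking_metrics(detect_tracers(img2, filter_isolated = FALSE),
                              detect_interface(img2), ps)
  expect_gt(deeper$L_max_cm, base$L_max_cm)
  expect_lte(deeper$L_mean_cm, deeper$L_max_cm)
})

test_that("an empty mask yields an explicit missing-value record with warning", {
  img <- flat_image()
  m <- detect_tracers(img)
  i <- detect_interface(img)
  expect_warning(met <- reworking_metrics(m, i, img$pixel_size), "empty")
  expect_true(is.na(met$L_med_cm))
  expect_equal(met$n_tracer_px, 0L)
  expect_false(is.na(met$SBR_cm))
})

test_that("pipeline statistics equal brute-force statistics over ground truth", {
  # the cross-module oracle at moderate scale; the acceptance suite repeats
  # it over 20 seeds
  g <- make_profile_image(species_archetype("mixture"), 260, 400,
                          pixel_size = 0.025, seed = 23, n_particles = 1500)
  met <- fspi_analyse(g$image)
  want <- brute_depth_stats(g$ground_truth$tracer_depths)
  tol <- 0.025 + 1e-9                     # one pixel
  expect_lte(abs(met$L_med_cm - want["L_med"]), tol)
  expect_lte(abs(met$L_mean_cm - want["L_mean"]), tol)
  expect_lte(abs(met$L_max_cm - want["L_max"]), tol)
  expect_lte(abs(met$SBR_cm - g$ground_truth$relief_cm), tol)
})
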