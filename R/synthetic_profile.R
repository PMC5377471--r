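# Synthetic f-SPI profile images with exact per-pixel ground truth.

#' Construct a sediment profile image object
#'
#' A profile image is one composite photographed face of an aquarium: RGB
#' pixels (values in [0, 1]), rows increasing downward, with a known physical
#' pixel size.  The default pixel size matches a 10-megapixel sediment
#' profile camera resolving 56 x 56 um of sediment per pixel.
#'
#' @param pixels h x w x 3 numeric array in [0, 1].
#' @param pixel_size physical pixel size in cm (default 56 um = 0.0056 cm).
#' @param aquarium_id,face_id identifier labels.
#' @return Object of class \code{"profile_image"}.
#' @export
profile_image <- function(pixels, pixel_size = 0.0056,
                          aquarium_id = "aq1", face_id = "composite") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 2, dim(pixels)[2] >= 2,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 aquarium_id = aquarium_id, face_id = face_id),
            class = "profile_image")
}

#' @export
print.profile_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<profile_image> %s/%s: %d x %d px, %.4g cm/px (%.2f x %.2f cm)\n",
              x$aquarium_id, x$face_id, d[1], d[2], x$pixel_size,
              d[1] * x$pixel_size, d[2] * x$pixel_size))
  invisible(x)
}

#' Generate a synthetic tracer profile image with known ground truth
#'
#' Renders a dark water column above a rough sediment--water interface, a
#' noisy sediment matrix, and fluorescent tracer particles (saturated
#' magenta, mimicking pink luminophores under UV light) redistributed
#' downward by a species archetype.  Tracer depths below the local interface
#' are drawn from a half-normal distribution with scale
#' \code{mixing_depth_scale} (for the mixture archetype, an equal-weight
#' mixture of the component kernels); a small fraction of "deep transport"
#' particles is placed along burrow tracks down to \code{burrow_max_depth},
#' reproducing the contrast between frequent surficial mixing and rare deep
#' nonlocal transport.
#'
#' Each particle is rendered as two horizontally adjacent pixels that follow
#' the local interface (a ~80 um particle imaged at 56 um/px with UV bloom
#' spans about two pixels), so no true tracer pixel is isolated and the
#' per-pixel depth is an exact multiple of the pixel size.  The ground truth
#' records the realised depth of every distinct tracer pixel, the quantity
#' the f-SPI stage estimates.
#'
#' @param archetype a \code{\link{species_archetype}}.
#' @param width_px,height_px image dimensions in pixels (>= 8).
#' @param pixel_size physical pixel size in cm.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_particles number of tracer particles to place.
#' @param deep_fraction fraction of particles routed along deep burrow
#'   tracks (default 0.02).
#' @param water_depth_cm thickness of the water column at the image top.
#' @param interface_amplitude_cm standard deviation of the interface
#'   elevation profile (controls the true surface boundary roughness).
#' @param matrix_noise_sd per-channel Gaussian noise on the sediment matrix
#'   (0 disables noise; exact-recovery tests use 0).
#' @param aquarium_id label carried into the image object.
#' @return A list with elements \code{image} (a \code{profile_image}) and
#'   \code{ground_truth}: \code{tracer_depths} (cm, one per distinct tracer
#'   pixel -- the pixel-weighted quantity the f-SPI stage estimates),
#'   \code{particle_depths} (cm, one per placed particle, before pixel
#'   collisions), \code{tracer_px} (matrix of row/col indices),
#'   \code{interface_elevation} (true first sediment row per column) and
#'   \code{relief_cm} (true max - min interface elevation).
#' @examples
#' g <- make_profile_image(species_archetype("u_tube"), 160, 240,
#'                         pixel_size = 0.025, seed = 1, n_particles = 500)
#' range(g$ground_truth$tracer_depths)
#' @export
make_profile_image <- function(archetype, width_px = 600L, height_px = 1800L,
                               pixel_size = 0.0056, seed = 1L,
                               n_particles = 4000L, deep_fraction = 0.02,
                               water_depth_cm = 1, interface_amplitude_cm = 0.12,
                               matrix_noise_sd = 0.03, aquarium_id = "aq1") {
  stopifnot(inherits(archetype, "species_archetype"))
  if (width_px < 8 || height_px < 8) stop("image dimensions must be >= 8 px")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (n_particles < 1) stop("n_particles must be >= 1")
  sediment_height_cm <- height_px * pixel_size - water_depth_cm
  scales <- if (archetype$name == "mixture") {
    vapply(archetype$components, `[[`, 0, "mixing_depth_scale")
  } else archetype$mixing_depth_scale
  if (max(scales) > sediment_height_cm) {
    stop("mixing_depth_scale exceeds the physical sediment height of the image")
  }

  set.seed(derive_seed(seed, 101L))
  w <- as.integer(width_px); h <- as.integer(height_px)

  # rough interface: smoothed Gaussian random walk, slope-limited to 1 px/col
  base_row <- max(2L, round(water_depth_cm / pixel_size))
  dev <- cumsum(rnorm(w))
  sig <- max(3, round(w / 40))
  kern <- exp(-0.5 * (seq(-3 * sig, 3 * sig) / sig)^2)
  dev <- as.numeric(stats::filter(c(rep(dev[1], 3 * sig), dev,
                                    rep(dev[w], 3 * sig)),
                                  kern / sum(kern), sides = 2))
  dev <- dev[(3 * sig + 1):(3 * sig + w)]
  s <- sd(dev)
  dev <- if (s > 0) (dev - mean(dev)) / s * (interface_amplitude_cm / pixel_size)
         else rep(0, w)
  elev <- base_row + round(dev)
  for (j in seq_len(w - 1L) + 1L) {   # limit slope so particle pairs stay 8-adjacent
    elev[j] <- min(max(elev[j], elev[j - 1L] - 1L), elev[j - 1L] + 1L)
  }
  elev <- pmin(pmax(elev, 2L), h - 5L)

  # particle depths: half-normal bulk + deep-transport tail along burrow tracks
  n <- as.integer(n_particles)
  n_deep <- round(deep_fraction * n)
  n_sh <- n - n_deep
  if (length(scales) > 1L) {
    comp <- sample.int(length(scales), n_sh, replace = TRUE)
    d_sh <- abs(rnorm(n_sh, 0, scales[comp]))
  } else {
    d_sh <- abs(rnorm(n_sh, 0, scales))
  }
  c_sh <- sample.int(w - 1L, n_sh, replace = TRUE)
  if (n_deep > 0) {
    n_tracks <- max(1L, as.integer(archetype$burrow_count))
    tracks <- sample.int(w - 1L, n_tracks, replace = n_tracks >= w - 1L)
    c_dp <- pmin(pmax(tracks[sample.int(n_tracks, n_deep, replace = TRUE)] +
                        round(rnorm(n_deep, 0, 2)), 1L), w - 1L)
    d_dp <- runif(n_deep, 0, min(archetype$burrow_max_depth,
                                 sediment_height_cm - 0.1))
    cols <- c(c_sh, c_dp); depths <- c(d_sh, d_dp)
  } else {
    cols <- c_sh; depths <- d_sh
  }
  dpx <- floor(depths / pixel_size)
  cap <- (h - 2L) - pmax(elev[cols], elev[cols + 1L])
  dpx <- pmin(dpx, cap)

  # two interface-following pixels per particle; collapse collisions
  r1 <- elev[cols] + dpx;        c1 <- cols
  r2 <- elev[cols + 1L] + dpx;   c2 <- cols + 1L
  px <- unique(cbind(row = c(r1, r2), col = c(c1, c2)))
  depths_px <- (px[, 1L] - elev[px[, 2L]]) * pixel_size

  # render
  rowmat <- matrix(seq_len(h), h, w)
  elevmat <- matrix(elev, h, w, byrow = TRUE)
  water <- rowmat < elevmat
  img <- array(0, c(h, w, 3))
  base <- c(0.45, 0.38, 0.30); waterc <- c(0.02, 0.02, 0.10)
  for (ch in 1:3) {
    plane <- matrix(base[ch], h, w)
    plane[water] <- waterc[ch]
    if (matrix_noise_sd > 0) {
      plane <- plane + rnorm(h * w, 0, matrix_noise_sd)
      plane[plane < 0] <- 0; plane[plane > 1] <- 1
    }
    img[, , ch] <- plane
  }
  lin <- (px[, 2L] - 1L) * h + px[, 1L]
  img[lin] <- 1; img[lin + h * w] <- 0; img[lin + 2L * h * w] <- 0.8

  list(image = profile_image(img, pixel_size, aquarium_id = aquarium_id),
       ground_truth = list(tracer_depths = depths_px,
                           particle_depths = dpx * pixel_size,
                           tracer_px = px,
                           interface_elevation = elev,
                           relief_cm = (max(elev) - min(elev)) * pixel_size,
                           n_particles = n,
                           seed = seed))
}

#' Add isolated single-pixel colour speckle to a profile image
#'
#' Test utility emulating sensor speckle: a fraction of pixels is replaced by
#' the tracer colour at mutually isolated locations (no speck touches
#' another speck or a true tracer pixel), the failure mode the
#' single-pixel isolation filter in \code{\link{detect_tracers}} removes.
#'
#' @param image a \code{profile_image}.
#' @param frac fraction of pixels to corrupt (before isolation thinning).
#' @param seed integer seed.
#' @return A list: \code{image} (corrupted copy) and \code{noise_px}
#'   (row/col matrix of the specks actually placed).
#' @export
add_speckle_noise <- function(image, frac = 0.05, seed = 1L) {
  stopifnot(inherits(image, "profile_image"), frac >= 0, frac < 1)
  set.seed(derive_seed(seed, 909L))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  occupied <- detect_tracers(image, filter_isolated = FALSE)$mask
  cand <- sample.int(h * w, round(frac * h * w))
  taken <- neighbour_count8(occupied) > 0 | occupied
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    r <- (cand[i] - 1L) %% h + 1L; cc <- (cand[i] - 1L) %/% h + 1L
    if (!taken[r, cc]) {
      keep[i] <- TRUE
      taken[max(1L, r - 1L):min(h, r + 1L), max(1L, cc - 1L):min(w, cc + 1L)] <- TRUE
    }
  }
  cand <- cand[keep]
  px[cand] <- 1; px[cand + h * w] <- 0; px[cand + 2L * h * w] <- 0.8
  list(image = profile_image(px, image$pixel_size, image$aquarium_id,
                             image$face_id),
       noise_px = cbind(row = (cand - 1L) %% h + 1L,
                        col = (cand - 1L) %/% h + 1L))
}
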