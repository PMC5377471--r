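# f-SPI: fluorescent tracer detection, sediment-water interface extraction,
# and the particle-reworking summary statistics.

#' Colour rule for tracer detection
#'
#' HSV window selecting the fluorescent tracer colour: hue around magenta
#' (pink luminophores under UV), high saturation, value above a floor.
#'
#' @param hue_range permitted hue interval on [0, 1] (magenta ~ 0.87).
#' @param s_min minimum saturation.
#' @param v_min minimum value (brightness floor).
#' @return A list of class \code{"color_rule"}.
#' @export
tracer_color_rule <- function(hue_range = c(0.75, 0.97), s_min = 0.5,
                              v_min = 0.3) {
  stopifnot(length(hue_range) == 2, hue_range[1] < hue_range[2])
  structure(list(hue_range = hue_range, s_min = s_min, v_min = v_min),
            class = "color_rule")
}

#' Detect fluorescent tracer pixels in a profile image
#'
#' Marks pixels matching the tracer colour rule, then removes isolated
#' single pixels (no true 8-neighbour) as sensor speckle.  Tracer particles
#' image across at least two adjacent pixels, so the isolation filter cannot
#' remove true signal, while it protects the maximum mixed depth -- a single
#' order statistic -- from single-pixel noise.
#'
#' @param image a \code{\link{profile_image}}.
#' @param color_rule a \code{\link{tracer_color_rule}}.
#' @param filter_isolated remove isolated single pixels (default TRUE).
#' @return Object of class \code{"tracer_mask"}: logical \code{mask} aligned
#'   to the image and \code{n_tracer_px}.  An empty mask is legal.
#' @export
detect_tracers <- function(image, color_rule = tracer_color_rule(),
                           filter_isolated = TRUE) {
  stopifnot(inherits(image, "profile_image"),
            inherits(color_rule, "color_rule"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- rgb2hsv(rgb, maxColorValue = 1)
  ok <- hsv[1, ] >= color_rule$hue_range[1] &
        hsv[1, ] <= color_rule$hue_range[2] &
        hsv[2, ] >= color_rule$s_min &
        hsv[3, ] >= color_rule$v_min
  mask <- matrix(ok, h, w)
  if (filter_isolated && any(mask)) {
    mask <- mask & (neighbour_count8(mask) > 0L)
  }
  structure(list(mask = mask, n_tracer_px = sum(mask)), class = "tracer_mask")
}

#' Detect the sediment--water interface in a profile image
#'
#' Scans each column top-down for the first pixel whose luminance exceeds
#' the sediment threshold (water is dark, sediment bright), then smooths the
#' per-column elevations with a running median to remove single-column
#' spikes.  Columns where no pixel exceeds the threshold are flagged
#' invalid; if more than half the columns are invalid the image is
#' considered degraded and an error is raised.
#'
#' @param image a \code{\link{profile_image}}.
#' @param luminance_threshold scalar in (0, 1); default: Otsu split of the
#'   image luminance histogram.
#' @param median_window odd window width (columns) of the running median
#'   (default 11).
#' @return Object of class \code{"interface_profile"}: integer
#'   \code{elevation} (first sediment row per column, after smoothing),
#'   logical \code{valid}, and the threshold used.
#' @export
detect_interface <- function(image, luminance_threshold = NULL,
                             median_window = 11L) {
  stopifnot(inherits(image, "profile_image"))
  median_window <- as.integer(median_window)
  if (median_window %% 2L == 0L) median_window <- median_window + 1L
  px <- image$pixels
  lum <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  if (is.null(luminance_threshold)) {
    luminance_threshold <- otsu_threshold(lum, max_gray = 1)
  }
  above <- lum > luminance_threshold
  first_hit <- apply(above, 2L, function(colv) {
    i <- which(colv)
    if (length(i)) i[1L] else NA_integer_
  })
  valid <- !is.na(first_hit)
  if (mean(valid) < 0.5) {
    stop("degraded image: more than 50% of columns have no sediment signal")
  }
  elev <- first_hit
  elev[!valid] <- round(median(first_hit[valid]))
  k <- min(median_window, length(elev) - (1 - length(elev) %% 2))
  if (k >= 3L) elev <- as.integer(round(stats::runmed(elev, k)))
  structure(list(elevation = elev, valid = valid,
                 luminance_threshold = luminance_threshold),
            class = "interface_profile")
}

#' Particle-reworking metrics from a tracer mask and interface profile
#'
#' Converts each tracer pixel to a depth below the local sediment--water
#' interface of its own column (pixels above the local interface count as
#' depth 0: tracer resting on the surface) and summarises:
#' \code{L_med} (median mixed depth, typical short-term mixing),
#' \code{L_mean} (mean mixed depth, time-integrated mixing),
#' \code{L_max} (maximum mixed depth, rare deep transport), and \code{SBR}
#' (surface boundary roughness, max - min valid interface elevation).
#' Depths are pixel-weighted and reported in cm.
#'
#' @param mask a \code{\link{detect_tracers}} result.
#' @param interface a \code{\link{detect_interface}} result.
#' @param pixel_size physical pixel size in cm.
#' @param aquarium_id label copied into the output row.
#' @return A one-row data.frame of class \code{"reworking_metrics"} with
#'   columns \code{aquarium_id, L_med_cm, L_mean_cm, L_max_cm, SBR_cm,
#'   n_tracer_px}.  With no tracer pixels the depth statistics are NA and a
#'   warning is raised.
#' @examples
#' g <- make_profile_image(species_archetype("i_shaft"), 200, 300,
#'                         pixel_size = 0.02, seed = 3, n_particles = 800)
#' m <- detect_tracers(g$image)
#' i <- detect_interface(g$image)
#' reworking_metrics(m, i, g$image$pixel_size)
#' @export
reworking_metrics <- function(mask, interface, pixel_size,
                              aquarium_id = "aq1") {
  stopifnot(inherits(mask, "tracer_mask"),
            inherits(interface, "interface_profile"),
            pixel_size > 0,
            ncol(mask$mask) == length(interface$elevation))
  sbr <- if (any(interface$valid)) {
    diff(range(interface$elevation[interface$valid])) * pixel_size
  } else NA_real_
  if (mask$n_tracer_px == 0L) {
    warning("empty tracer mask: depth statistics undefined")
    out <- data.frame(aquarium_id = aquarium_id, L_med_cm = NA_real_,
                      L_mean_cm = NA_real_, L_max_cm = NA_real_,
                      SBR_cm = sbr, n_tracer_px = 0L,
                      stringsAsFactors = FALSE)
    class(out) <- c("reworking_metrics", "data.frame")
    return(out)
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  depths <- pmax(0L, idx[, 1L] - interface$elevation[idx[, 2L]]) * pixel_size
  out <- data.frame(aquarium_id = aquarium_id,
                    L_med_cm = median(depths),
                    L_mean_cm = mean(depths),
                    L_max_cm = max(depths),
                    SBR_cm = sbr,
                    n_tracer_px = mask$n_tracer_px,
                    stringsAsFactors = FALSE)
  class(out) <- c("reworking_metrics", "data.frame")
  out
}

#' Full f-SPI analysis of one profile image
#'
#' Convenience wrapper: tracer detection + interface detection +
#' \code{\link{reworking_metrics}}.
#'
#' @inheritParams detect_tracers
#' @inheritParams detect_interface
#' @return See \code{\link{reworking_metrics}}.
#' @export
fspi_analyse <- function(image, color_rule = tracer_color_rule(),
                         luminance_threshold = NULL, median_window = 11L) {
  m <- detect_tracers(image, color_rule)
  i <- detect_interface(image, luminance_threshold, median_window)
  reworking_metrics(m, i, image$pixel_size, aquarium_id = image$aquarium_id)
}
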