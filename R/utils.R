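# Shared small helpers: seed derivation, thresholds, filters, core geometry.

#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from explicit integer seeds.  Stages
#' derive their own sub-seeds with this helper so that one master seed fixes
#' an entire pipeline run without sharing random state between stages.
#'
#' @param seed master integer seed.
#' @param k stream index (non-negative integer).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  as.integer((abs(seed) * 48271 + k * 16807 + 12345) %% 2147483629)
}

#' Otsu threshold of a gray-level sample
#'
#' Bimodal histogram split used as the default segmentation threshold (the
#' gray level separating dense sediment from burrow voids, or dark water from
#' sediment in profile luminance).  Thin wrapper over \code{EBImage::otsu}.
#'
#' @param x numeric vector/array of gray levels.
#' @param max_gray full-scale value (255 for 8-bit volumes, 1 for luminance).
#' @return Threshold on the same scale as \code{x}.
#' @export
otsu_threshold <- function(x, max_gray = 255) {
  v <- as.numeric(x) / max_gray
  v <- v[is.finite(v)]
  v[v < 0] <- 0; v[v > 1] <- 1
  EBImage::otsu(matrix(v, ncol = 1L), range = c(0, 1), levels = 256L) * max_gray
}

# 2-D median filter on a small matrix (used to clean the per-(x,y) surface
# elevation map).  radius 1 -> 3x3 window, 2 -> 5x5.  Edges use the available
# part of the window.
median_filter2d <- function(m, radius = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  off <- seq.int(-radius, radius)
  stack <- matrix(NA_real_, nr * nc, length(off)^2)
  k <- 0L
  for (di in off) for (dj in off) {
    k <- k + 1L
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    stack[, k] <- m[ri, cj]
  }
  matrix(apply(stack, 1L, median), nr, nc)
}

# count of TRUE 8-neighbours for each cell of a logical matrix
neighbour_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cnt <- cnt + pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  cnt
}

#' Habitat volume of an experimental aquarium
#'
#' Internal volume of the two core designs used for benthic mesocosms: a
#' square-footprint aquarium (for profile imaging through flat walls) and a
#' circular core (for rotational CT imaging).  The two designs are chosen to
#' share the same habitat volume.
#'
#' @param shape \code{"circular"} or \code{"square"}.
#' @param diameter_cm internal diameter (circular cores).
#' @param width_cm internal footprint width (square cores).
#' @param height_cm internal height.
#' @return Volume in cm^3.
#' @examples
#' aquarium_volume("circular", diameter_cm = 10, height_cm = 15)
#' aquarium_volume("square", width_cm = 8.86, height_cm = 15)
#' @export
aquarium_volume <- function(shape = c("circular", "square"),
                            diameter_cm = 10, width_cm = 8.86,
                            height_cm = 15) {
  shape <- match.arg(shape)
  stopifnot(height_cm > 0)
  if (shape == "circular") {
    stopifnot(diameter_cm > 0)
    pi * (diameter_cm / 2)^2 * height_cm
  } else {
    stopifnot(width_cm > 0)
    width_cm^2 * height_cm
  }
}

#' Areal biomass density of a stocked aquarium
#'
#' Converts a fixed wet-weight faunal biomass per aquarium into an areal
#' density over the sediment footprint, the field-comparable unit.
#'
#' @param mass_g wet weight added per aquarium (g).
#' @param width_cm internal width of the square footprint (cm).
#' @return Density in g m^-2.
#' @examples
#' biomass_density(1, 8.86)  # ~127 g m^-2
#' @export
biomass_density <- function(mass_g, width_cm) {
  stopifnot(mass_g >= 0, width_cm > 0)
  mass_g / (width_cm / 100)^2
}

# FNV-1a 32-bit hash of a character scalar; used to stamp pipeline outputs so
# tables from different configurations are distinguishable.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256                       # xor only touches the low byte
    h <- h - lo8 + bitwXor(lo8, b %% 256)
    # 32-bit modular multiply by the FNV prime without double overflow
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
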