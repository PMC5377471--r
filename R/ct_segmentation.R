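# Threshold-based seed-point region growing for burrow void segmentation.

# connected components of a logical 3-D mask; returns integer membership
# array (0 outside mask) and component sizes.  Adjacency built explicitly
# and resolved with igraph's C components routine.
mask_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3, connectivity %in% c(6L, 26L))
  idx <- which(mask)
  memb <- array(0L, dims)
  if (length(idx) == 0L) return(list(membership = memb, sizes = integer(0)))
  rank <- array(0L, dims)
  rank[idx] <- seq_along(idx)
  nxy <- dims[1] * dims[2]
  x <- (idx - 1L) %% dims[1] + 1L
  y <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  z <- (idx - 1L) %/% nxy + 1L
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    o[o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0))), ,
      drop = FALSE]           # 13 forward offsets
  }
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    xn <- x + offs[i, 1]; yn <- y + offs[i, 2]; zn <- z + offs[i, 3]
    ok <- xn >= 1L & xn <= dims[1] & yn >= 1L & yn <= dims[2] &
          zn >= 1L & zn <= dims[3]
    nb <- rank[cbind(xn[ok], yn[ok], zn[ok])]
    hit <- nb > 0L
    from <- c(from, rank[idx[ok]][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  cm <- igraph::components(g)
  memb[idx] <- cm$membership
  list(membership = memb, sizes = as.integer(cm$csize))
}

#' Seed-point region growing of sub-threshold voxels
#'
#' Segments burrow voids: each seed expands to the maximal connected set of
#' voxels with gray level <= \code{threshold} under the requested
#' connectivity (26 by default, so thin diagonal burrow segments do not
#' fragment).  Seeds falling in the same connected component merge into one
#' region; labels are deterministic, ordered by seed order.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param seeds integer matrix (n x 3) of voxel coordinates (x, y, z).
#' @param threshold gray level; voxels with gray <= threshold are growable.
#' @param connectivity 6 (face) or 26 (face+edge+corner).
#' @return Object of class \code{"burrow_segmentation"}: \code{labels}
#'   (integer array, 0 = matrix), \code{components} (data.frame of id,
#'   voxel_count and the first seed of each region), \code{threshold},
#'   \code{connectivity}.
#' @examples
#' v <- array(200, c(10, 10, 10)); v[4:6, 4:6, 4:6] <- 20
#' seg <- grow_regions(voxel_volume(v, 0.1), rbind(c(5, 5, 5)), threshold = 100)
#' seg$components$voxel_count  # 27
#' @export
grow_regions <- function(volume, seeds, threshold, connectivity = 26L) {
  stopifnot(inherits(volume, "voxel_volume"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  if (nrow(seeds) == 0L) stop("empty seed list: supply seeds or use auto_seed()")
  dims <- dim(volume$voxels)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (any(s < 1L) || any(s > dims)) {
      stop(sprintf("seed %d (%d,%d,%d) is outside the volume", i, s[1], s[2], s[3]))
    }
    if (volume$voxels[s[1], s[2], s[3]] > threshold) {
      stop(sprintf("seed %d (%d,%d,%d) has gray %g above threshold %g",
                   i, s[1], s[2], s[3], volume$voxels[s[1], s[2], s[3]],
                   threshold))
    }
  }
  cm <- mask_components(volume$voxels <= threshold, connectivity)
  seed_comp <- cm$membership[seeds]
  keep <- unique(seed_comp)                      # order of first appearance
  relabel <- integer(length(cm$sizes))
  relabel[keep] <- seq_along(keep)
  labels <- array(0L, dims)
  inkeep <- cm$membership != 0L & relabel[pmax(cm$membership, 1L)] > 0L &
            cm$membership %in% keep
  labels[inkeep] <- relabel[cm$membership[inkeep]]
  first_seed <- seeds[match(keep, seed_comp), , drop = FALSE]
  comps <- data.frame(id = seq_along(keep),
                      voxel_count = cm$sizes[keep],
                      seed_x = first_seed[, 1], seed_y = first_seed[, 2],
                      seed_z = first_seed[, 3])
  structure(list(labels = labels, components = comps, threshold = threshold,
                 connectivity = connectivity),
            class = "burrow_segmentation")
}

#' Estimate the sediment surface elevation map of a CT volume
#'
#' Scans each (x, y) column top-down for the first voxel whose gray exceeds
#' the threshold (first sediment voxel below the dark water layer) and
#' median-filters the resulting elevation map to remove noise hits and dips
#' at burrow openings.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param threshold gray level; default Otsu on the whole volume.
#' @param filter_radius 2-D median filter radius (2 -> 5x5 window).
#' @return List: \code{surface_z} (per-(x,y) z index of the first sediment
#'   voxel) and the threshold used.
#' @export
estimate_surface <- function(volume, threshold = NULL, filter_radius = 2L) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- volume$voxels
  if (is.null(threshold)) threshold <- otsu_threshold(v, 255)
  dims <- dim(v)
  above <- v > threshold
  # first TRUE along z per (x,y): argmax over the z dimension
  flat <- matrix(above, dims[1] * dims[2], dims[3])
  any_hit <- rowSums(flat) > 0
  first <- max.col(flat, ties.method = "first")
  first[!any_hit] <- dims[3]
  # burrow openings leave deep first-hit outliers that are lumen, not
  # surface: cap at median + 3 MAD before smoothing
  cap <- median(first) + 3 * stats::mad(first)
  first <- pmin(first, cap)
  sz <- matrix(first, dims[1], dims[2])
  if (filter_radius > 0) sz <- median_filter2d(sz, filter_radius)
  list(surface_z = matrix(as.integer(round(sz)), dims[1], dims[2]),
       threshold = threshold)
}

#' Automatically seed sub-threshold components below the sediment surface
#'
#' Places one seed per connected sub-threshold component that lies below the
#' sediment surface and has at least \code{min_component_voxels} voxels.
#' Components consisting only of the water region above the surface are
#' excluded (the below-surface restriction removes them).  Seeds are the
#' lowest-linear-index voxel of each component, so seeding is deterministic.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param threshold gray level.
#' @param min_component_voxels minimum component size to receive a seed.
#' @param surface_z per-(x,y) surface map; default \code{\link{estimate_surface}}.
#' @param connectivity 6 or 26.
#' @return Integer matrix (n x 3) of seed coordinates; zero rows if nothing
#'   qualifies.
#' @export
auto_seed <- function(volume, threshold, min_component_voxels = 27L,
                      surface_z = NULL, connectivity = 26L) {
  stopifnot(inherits(volume, "voxel_volume"))
  dims <- dim(volume$voxels)
  if (is.null(surface_z)) surface_z <- estimate_surface(volume, threshold)$surface_z
  zplane <- aperm(array(surface_z, c(dims[1], dims[2], dims[3])), c(1, 2, 3))
  zidx <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  below <- zidx >= zplane
  mask <- (volume$voxels <= threshold) & below
  cm <- mask_components(mask, connectivity)
  ids <- which(cm$sizes >= min_component_voxels)
  if (!length(ids)) return(matrix(integer(0), 0, 3))
  seeds <- t(vapply(ids, function(id) {
    lin <- which(cm$membership == id)[1L]
    c((lin - 1L) %% dims[1] + 1L,
      ((lin - 1L) %/% dims[1]) %% dims[2] + 1L,
      (lin - 1L) %/% (dims[1] * dims[2]) + 1L)
  }, integer(3)))
  storage.mode(seeds) <- "integer"
  seeds
}

#' Segment burrow voids of a CT volume end-to-end
#'
#' The full segmentation stage: estimate the surface elevation map, choose a
#' gray threshold (Otsu split of the below-surface histogram by default),
#' exclude the water column, auto-seed, and grow regions.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param threshold \code{"otsu"} or a numeric gray level.
#' @param connectivity 6 or 26.
#' @param min_component_voxels minimum component size to keep.
#' @return List: \code{segmentation} (a \code{burrow_segmentation} with the
#'   water column excluded), \code{surface_z}, \code{threshold},
#'   \code{seeds}.  With no qualifying component the segmentation is empty
#'   (all-zero labels).
#' @export
segment_burrows <- function(volume, threshold = "otsu", connectivity = 26L,
                            min_component_voxels = 27L) {
  stopifnot(inherits(volume, "voxel_volume"))
  dims <- dim(volume$voxels)
  surf <- estimate_surface(volume)
  if (identical(threshold, "otsu")) {
    zidx <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
    below <- zidx >= array(surf$surface_z, dims)
    threshold <- otsu_threshold(volume$voxels[below], 255)
  }
  stopifnot(is.numeric(threshold))
  # wall off the water column so growth cannot escape through burrow openings
  zidx <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  below <- zidx >= array(surf$surface_z, dims)
  vmasked <- volume$voxels
  vmasked[!below] <- 255
  vol2 <- voxel_volume(vmasked, volume$voxel_size, volume$up_axis,
                       volume$aquarium_id)
  seeds <- auto_seed(vol2, threshold, min_component_voxels,
                     surface_z = surf$surface_z, connectivity = connectivity)
  seg <- if (nrow(seeds) == 0L) {
    structure(list(labels = array(0L, dims),
                   components = data.frame(id = integer(0),
                                           voxel_count = integer(0),
                                           seed_x = integer(0),
                                           seed_y = integer(0),
                                           seed_z = integer(0)),
                   threshold = threshold, connectivity = connectivity),
              class = "burrow_segmentation")
  } else {
    grow_regions(vol2, seeds, threshold, connectivity)
  }
  list(segmentation = seg, surface_z = surf$surface_z, threshold = threshold,
       seeds = seeds)
}
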