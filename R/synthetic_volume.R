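# Synthetic micro-CT volumes: burrow systems carved as low-density voids
# into a bright sediment matrix, with the exact carved voxel set as ground
# truth.

#' Construct a voxel volume object
#'
#' A reconstructed CT volume of one aquarium: 8-bit gray levels where
#' brighter voxels are denser material (sediment) and darker voxels are less
#' dense (burrow voids, water).  Axes are (x, y, z) with z = 1 the top slice
#' and z increasing downward (up axis \code{"-z"}).  The default voxel size
#' matches an 81 um reconstruction.
#'
#' @param voxels 3-D numeric array, gray levels in 0..255.
#' @param voxel_size physical voxel edge in cm (default 81 um = 0.0081 cm).
#' @param up_axis only \code{"-z"} (z index 1 uppermost) is supported.
#' @param aquarium_id identifier label.
#' @return Object of class \code{"voxel_volume"}.
#' @export
voxel_volume <- function(voxels, voxel_size = 0.0081, up_axis = "-z",
                         aquarium_id = "aq1") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, all(dim(voxels) >= 2),
            voxel_size > 0)
  if (!identical(up_axis, "-z")) {
    stop("only up_axis = '-z' (z slice 1 at the top) is supported")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size, up_axis = up_axis,
                 aquarium_id = aquarium_id), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_volume> %s: %d x %d x %d voxels, %.4g cm/voxel\n",
              x$aquarium_id, d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

# integer offsets within a sphere of given radius (voxels)
sphere_stencil <- function(r) {
  ir <- ceiling(r)
  g <- expand.grid(dx = -ir:ir, dy = -ir:ir, dz = -ir:ir)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE])
}

# carve spheres of radius r_vox along a polyline of (x,y,z) voxel coords;
# returns unique linear indices within the grid
carve_path <- function(path, r_vox, dims) {
  if (nrow(path) == 0) return(integer(0))
  # densify to ~0.5-voxel spacing
  pts <- path
  if (nrow(path) > 1) {
    segs <- lapply(seq_len(nrow(path) - 1L), function(i) {
      a <- path[i, ]; b <- path[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      n <- max(1L, ceiling(len / 0.5))
      t <- seq(0, 1, length.out = n + 1L)[-1L]
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
            a[3] + t * (b[3] - a[3]))
    })
    pts <- rbind(path[1, , drop = FALSE], do.call(rbind, segs))
  }
  ctr <- unique(round(pts))
  st <- sphere_stencil(r_vox)
  x <- rep(ctr[, 1], each = nrow(st)) + st[, 1]
  y <- rep(ctr[, 2], each = nrow(st)) + st[, 2]
  z <- rep(ctr[, 3], each = nrow(st)) + st[, 3]
  ok <- x >= 1 & x <= dims[1] & y >= 1 & y <= dims[2] & z >= 1 & z <= dims[3]
  unique((z[ok] - 1) * dims[1] * dims[2] + (y[ok] - 1) * dims[1] + x[ok])
}

# entry points with pairwise separation, by rejection sampling
place_entries <- function(n, dims, margin, min_sep, max_tries = 400L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo <- margin + 1; hix <- dims[1] - margin; hiy <- dims[2] - margin
  if (hix <= lo || hiy <= lo) stop("volume too small for burrow radius/margin")
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    p <- c(runif(1, lo, hix), runif(1, lo, hiy))
    if (placed == 0L ||
        all(sqrt((pts[seq_len(placed), 1] - p[1])^2 +
                 (pts[seq_len(placed), 2] - p[2])^2) >= min_sep)) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) break
    }
  }
  if (placed < n) {       # dense stocking: allow closer packing
    for (j in (placed + 1L):n) {
      pts[j, ] <- c(runif(1, lo, hix), runif(1, lo, hiy))
    }
  }
  pts
}

# correlated random walk for a branched gallery; returns list of polylines
gallery_paths <- function(entry, z_surface, depth_target_vox, branching_rate,
                          voxel_size, dims, margin, max_walkers = 12L) {
  paths <- list()
  # queue of walkers: position, direction, depth target (voxels)
  queue <- list(list(pos = c(entry, z_surface - 2), dir = c(0, 0, 1),
                     target = depth_target_vox))
  p_branch <- min(0.9, branching_rate * voxel_size)  # per 1-voxel step
  n_spawned <- 1L
  while (length(queue) > 0) {
    wk <- queue[[1]]; queue <- queue[-1]
    pos <- wk$pos; dir <- wk$dir
    pts <- matrix(pos, 1, 3)
    steps <- 0L
    while ((pos[3] - z_surface) < wk$target && steps < 6L * wk$target + 60L) {
      steps <- steps + 1L
      dir <- dir * 0.8 + rnorm(3, 0, 0.35) + c(0, 0, 0.18)
      dir <- dir / sqrt(sum(dir^2))
      nxt <- pos + dir
      if (nxt[1] < margin + 1 || nxt[1] > dims[1] - margin) dir[1] <- -dir[1]
      if (nxt[2] < margin + 1 || nxt[2] > dims[2] - margin) dir[2] <- -dir[2]
      if (nxt[3] < 2) dir[3] <- abs(dir[3])
      pos <- pos + dir
      pts <- rbind(pts, pos)
      if (n_spawned < max_walkers && runif(1) < p_branch &&
          (pos[3] - z_surface) > 2) {
        n_spawned <- n_spawned + 1L
        bd <- dir * 0.3 + rnorm(3, 0, 0.6) + c(0, 0, 0.1)
        queue[[length(queue) + 1L]] <-
          list(pos = pos, dir = bd / sqrt(sum(bd^2)),
               target = runif(1, 0.5, 1) * depth_target_vox)
      }
    }
    paths[[length(paths) + 1L]] <- pts
  }
  paths
}

#' Generate a synthetic CT volume with carved burrow systems
#'
#' Carves archetype-specific void paths into a bright sediment matrix below
#' a water layer: a correlated-random-walk branched gallery
#' (\code{gallery_diffuser}), two vertical limbs joined by a semicircular
#' bend (\code{u_tube}), a single near-vertical shaft (\code{i_shaft}), or
#' the 1/3-scaled union of all three (\code{mixture}).  Every burrow opens
#' at the sediment surface.  Gaussian gray noise is added last.  The exact
#' set of carved below-surface voxels is returned as ground truth.
#'
#' @param archetype a \code{\link{species_archetype}}.
#' @param shape_xyz integer grid dimensions c(nx, ny, nz).
#' @param voxel_size voxel edge in cm.
#' @param noise_sd gray-level noise sd (0..255 scale; 0 for exact tests).
#' @param seed integer seed; identical seeds give bit-identical volumes.
#' @param water_depth_cm water layer thickness above the sediment surface.
#' @param matrix_gray,void_gray,water_gray gray levels of sediment, burrow
#'   lumen and water.
#' @param shaft_tilt_sd sd (radians) of the random tilt of I-shafts
#'   (0 gives an exactly vertical shaft, used by the analytic oracle tests).
#' @return A list: \code{volume} (a \code{\link{voxel_volume}}) and
#'   \code{ground_truth} with \code{burrow_voxel_set} (sorted linear indices
#'   of carved below-surface voxels), \code{surface_z} (per-(x,y) first
#'   sediment slice), \code{n_structures}, \code{max_void_depth_cm}.
#' @examples
#' g <- make_burrow_volume(species_archetype("i_shaft"), c(40, 40, 60),
#'                         voxel_size = 0.06, noise_sd = 0, seed = 2)
#' length(g$ground_truth$burrow_voxel_set)
#' @export
make_burrow_volume <- function(archetype, shape_xyz = c(96L, 96L, 200L),
                               voxel_size = 0.05, noise_sd = 8, seed = 1L,
                               water_depth_cm = 0.5, matrix_gray = 200,
                               void_gray = 30, water_gray = 25,
                               shaft_tilt_sd = 0.05) {
  stopifnot(inherits(archetype, "species_archetype"),
            length(shape_xyz) == 3, all(shape_xyz >= 8), voxel_size > 0,
            noise_sd >= 0)
  dims <- as.integer(shape_xyz)
  set.seed(derive_seed(seed, 202L))
  zs <- max(2L, round(water_depth_cm / voxel_size) + 1L)  # first sediment slice

  comps <- if (archetype$name == "mixture") archetype$components
           else list(archetype)
  for (a in comps) {
    if (a$burrow_count == 0L) next
    if (a$burrow_radius / voxel_size < 1) {
      stop("burrow_radius smaller than one voxel: increase resolution")
    }
    if (zs + a$burrow_max_depth / voxel_size + 2 > dims[3]) {
      stop("burrow_max_depth does not fit inside the volume")
    }
  }

  carved <- integer(0)
  n_structures <- 0L
  entries_all <- list()
  for (a in comps) {
    if (a$burrow_count == 0L) next
    r_vox <- a$burrow_radius / voxel_size
    d_vox <- a$burrow_max_depth / voxel_size
    span <- if (a$name == "u_tube") max(2 * r_vox + 3, 0.8 / voxel_size) else 0
    margin <- ceiling(r_vox) + 2L
    entries <- place_entries(a$burrow_count, dims, margin + ceiling(span),
                             min_sep = 2 * (r_vox + 2) + span)
    for (b in seq_len(a$burrow_count)) {
      e <- entries[b, ]
      paths <- switch(a$name,
        gallery_diffuser = gallery_paths(e, zs, d_vox, a$branching_rate,
                                         voxel_size, dims, margin),
        u_tube = {
          ang <- runif(1, 0, 2 * pi)
          u <- c(cos(ang), sin(ang))
          # keep both limbs inside the lateral margins
          far <- e + u * span
          if (far[1] < margin + 1 || far[1] > dims[1] - margin ||
              far[2] < margin + 1 || far[2] > dims[2] - margin) {
            u <- -u; far <- e + u * span
          }
          z_turn <- zs + d_vox - r_vox - span / 2
          theta <- seq(0, pi, length.out = 24)
          mid <- (e + far) / 2
          bend <- cbind(mid[1] - (span / 2) * cos(theta) * u[1],
                        mid[2] - (span / 2) * cos(theta) * u[2],
                        z_turn + (span / 2) * sin(theta))
          list(rbind(c(e, zs - 2), c(e, z_turn), bend,
                     c(far, z_turn), c(far, zs - 2)))
        },
        i_shaft = {
          tilt <- rnorm(2, 0, shaft_tilt_sd)
          bottom <- c(e + tilt * d_vox, zs + d_vox - r_vox)
          bottom[1] <- min(max(bottom[1], margin + 1), dims[1] - margin)
          bottom[2] <- min(max(bottom[2], margin + 1), dims[2] - margin)
          list(rbind(c(e, zs - 2), bottom))
        },
        stop("no carving model for archetype ", a$name))
      for (p in paths) carved <- c(carved, carve_path(p, r_vox, dims))
      n_structures <- n_structures + 1L
      entries_all[[n_structures]] <- c(e, archetype_n = match(a$name, c(
        "gallery_diffuser", "u_tube", "i_shaft")))
    }
  }
  carved <- unique(carved)

  vox <- array(matrix_gray, dims)
  if (zs > 1L) vox[, , seq_len(zs - 1L)] <- water_gray
  vox[carved] <- void_gray
  surface_z <- matrix(zs, dims[1], dims[2])
  # ground truth: carved voxels at/below the sediment surface
  if (length(carved)) {
    carved <- as.integer(carved)
    zc <- (carved - 1L) %/% (dims[1] * dims[2]) + 1L
    gt <- sort(carved[zc >= zs])
    depth_max <- max((zc[zc >= zs] - zs)) * voxel_size
  } else {
    gt <- integer(0); depth_max <- 0
  }
  if (noise_sd > 0) {
    vox <- vox + rnorm(length(vox), 0, noise_sd)
    vox[vox < 0] <- 0; vox[vox > 255] <- 255
  }
  vox <- round(vox)

  list(volume = voxel_volume(vox, voxel_size, aquarium_id = "aq1"),
       ground_truth = list(burrow_voxel_set = gt,
                           surface_z = surface_z,
                           entries = if (n_structures) do.call(rbind, entries_all)
                                     else matrix(numeric(0), 0, 3),
                           n_structures = n_structures,
                           max_void_depth_cm = depth_max,
                           seed = seed))
}
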