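# Burrow morphometrics: exact voxel-count volume, iso-surface mesh area,
# and maximum depth below the local sediment surface.

# --- separable Gaussian smoothing of a 3-D array (zero-padded) -------------
gauss_smooth3 <- function(a, sigma = 1) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * (seq(-r, r) / sigma)^2)
  k <- k / sum(k)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      sh <- j - r - 1L
      n <- dim(a)[ax]
      src <- seq_len(n) + sh
      ok <- src >= 1L & src <= n
      idx_dst <- which(ok); idx_src <- src[ok]
      if (ax == 1) out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * a[idx_src, , ]
      if (ax == 2) out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * a[, idx_src, ]
      if (ax == 3) out[, , idx_dst] <- out[, , idx_dst] + k[j] * a[, , idx_src]
    }
    a <- out
  }
  a
}

# --- marching tetrahedra ---------------------------------------------------
# Cube corners in binary order (x, y, z offsets):
#   1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0) 5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
# Six-tetrahedron decomposition around the 1-7 diagonal; face diagonals are
# consistent between neighbouring cubes, so the mesh is watertight.
.mt_corners <- cbind(x = c(0, 1, 1, 0, 0, 1, 1, 0),
                     y = c(0, 0, 1, 1, 0, 0, 1, 1),
                     z = c(0, 0, 0, 0, 1, 1, 1, 1))
.mt_tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# polygon (as ordered list of tet-corner pairs) cut by the iso-surface in a
# tetrahedron, for each of the 16 inside/outside sign codes
.mt_cases <- local({
  cases <- vector("list", 16L)
  for (code in 1:14) {
    inside <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
    outside <- setdiff(1:4, inside)
    if (length(inside) == 1L) {
      i <- inside
      cases[[code + 1L]] <- lapply(outside, function(o) c(i, o))
    } else if (length(inside) == 3L) {
      o <- outside
      cases[[code + 1L]] <- lapply(inside, function(i) c(i, o))
    } else {                                   # 2 in / 2 out -> quad
      i <- inside; o <- outside
      cases[[code + 1L]] <- list(c(i[1], o[1]), c(i[1], o[2]),
                                 c(i[2], o[2]), c(i[2], o[1]))
    }
  }
  cases
})

# iso-surface triangles of scalar field `a` at level `iso`.
# Returns a list of three n x 3 matrices (vertex coordinates per triangle
# corner), in voxel units, plus triangle centroids.
marching_tetrahedra <- function(a, iso = 0.5) {
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # linear index of corner 1 for every cell
  cx <- seq_len(nx - 1L); cy <- seq_len(ny - 1L); cz <- seq_len(nz - 1L)
  base <- outer(outer(cx, (cy - 1L) * nx, `+`), (cz - 1L) * nx * ny, `+`)
  corner_off <- .mt_corners[, 1] + .mt_corners[, 2] * nx +
                .mt_corners[, 3] * nx * ny
  v1 <- a[as.vector(base)]
  vals <- matrix(0, length(base), 8L)
  vals[, 1] <- v1
  for (j in 2:8) vals[, j] <- a[as.vector(base) + corner_off[j]]
  rng_lo <- vals[, 1]; rng_hi <- vals[, 1]
  for (j in 2:8) { rng_lo <- pmin(rng_lo, vals[, j]); rng_hi <- pmax(rng_hi, vals[, j]) }
  active <- which(rng_lo < iso & rng_hi >= iso)
  if (!length(active)) {
    z3 <- matrix(numeric(0), 0, 3)
    return(list(p1 = z3, p2 = z3, p3 = z3, centroid = z3))
  }
  vals <- vals[active, , drop = FALSE]
  lin0 <- as.vector(base)[active] - 1L
  x0 <- lin0 %% nx; y0 <- (lin0 %/% nx) %% ny; z0 <- lin0 %/% (nx * ny)

  P1 <- P2 <- P3 <- vector("list", 0L)
  interp <- function(ca, cb, va, vb, sel) {
    t <- (iso - va) / (vb - va)
    A <- .mt_corners[ca, , drop = FALSE]; B <- .mt_corners[cb, , drop = FALSE]
    cbind(x0[sel] + A[, 1] + t * (B[, 1] - A[, 1]),
          y0[sel] + A[, 2] + t * (B[, 2] - A[, 2]),
          z0[sel] + A[, 3] + t * (B[, 3] - A[, 3]))
  }
  for (ti in seq_len(nrow(.mt_tets))) {
    tc <- .mt_tets[ti, ]
    tv <- vals[, tc, drop = FALSE]
    code <- (tv[, 1] >= iso) + 2L * (tv[, 2] >= iso) +
            4L * (tv[, 3] >= iso) + 8L * (tv[, 4] >= iso)
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (!length(sel)) next
      edges <- .mt_cases[[cd + 1L]]
      pts <- lapply(edges, function(e) {
        interp(tc[e[1]], tc[e[2]], tv[sel, e[1]], tv[sel, e[2]], sel)
      })
      P1[[length(P1) + 1L]] <- pts[[1]]
      P2[[length(P2) + 1L]] <- pts[[2]]
      P3[[length(P3) + 1L]] <- pts[[3]]
      if (length(edges) == 4L) {             # quad -> second triangle
        P1[[length(P1) + 1L]] <- pts[[1]]
        P2[[length(P2) + 1L]] <- pts[[3]]
        P3[[length(P3) + 1L]] <- pts[[4]]
      }
    }
  }
  p1 <- do.call(rbind, P1); p2 <- do.call(rbind, P2); p3 <- do.call(rbind, P3)
  list(p1 = p1, p2 = p2, p3 = p3, centroid = (p1 + p2 + p3) / 3)
}

triangle_areas <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# mesh surface area (voxel^2 units) of a logical 3-D mask: Gaussian-smoothed
# indicator meshed at iso = 0.5.  Optionally returns triangles for filtering.
mask_mesh <- function(mask, sigma = 1, pad = 4L) {
  d <- dim(mask)
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask * 1
  f <- gauss_smooth3(f, sigma)
  m <- marching_tetrahedra(f, 0.5)
  # shift back to unpadded voxel coordinates (voxel centers at integers)
  for (nm in c("p1", "p2", "p3", "centroid")) m[[nm]] <- m[[nm]] + 1 - pad
  m
}

#' Burrow morphometrics from a segmentation
#'
#' Computes the three CT burrow descriptors:
#' \describe{
#'   \item{\code{B_vol_cm3}}{lumen volume: exact labelled voxel count times
#'     \code{voxel_size^3} (an indication of the extent of bioengineering).}
#'   \item{\code{B_SA_cm2}}{burrow wall surface area from a
#'     marching-tetrahedra iso-surface of the Gaussian-smoothed labelled set
#'     (staircase-free, unlike voxel-face counting); by default, mesh faces
#'     capping burrow openings at the sediment surface are excluded -- a
#'     lumen opening is not sediment--water interface created by the burrow
#'     wall.  Set \code{include_openings = TRUE} to keep them.}
#'   \item{\code{B_max_cm}}{maximum depth of any labelled voxel below the
#'     local surface elevation.}
#' }
#'
#' @param seg a \code{\link{grow_regions}}/\code{\link{segment_burrows}}
#'   segmentation (a \code{burrow_segmentation}).
#' @param volume the \code{\link{voxel_volume}} the segmentation came from.
#' @param surface_z per-(x,y) surface elevation map (z index); a flat plane
#'   at the shallowest labelled voxel is used when NULL.
#' @param include_openings keep mesh faces at the sediment-surface cap.
#' @param mesh_sigma Gaussian pre-smoothing sd (voxels) for the iso-surface.
#' @param aquarium_id label for the output row.
#' @return One-row data.frame of class \code{"burrow_metrics"}:
#'   \code{aquarium_id, B_max_cm, B_SA_cm2, B_vol_cm3, n_components}.
#'   An empty segmentation gives zeros.
#' @examples
#' v <- array(200, c(12, 12, 12)); v[5:8, 5:8, 5:8] <- 20
#' vol <- voxel_volume(v, 0.1)
#' seg <- grow_regions(vol, rbind(c(6, 6, 6)), threshold = 100)
#' burrow_metrics(seg, vol, surface_z = matrix(1L, 12, 12))
#' @export
burrow_metrics <- function(seg, volume, surface_z = NULL,
                           include_openings = FALSE, mesh_sigma = 1,
                           aquarium_id = NULL) {
  stopifnot(inherits(seg, "burrow_segmentation"),
            inherits(volume, "voxel_volume"),
            identical(dim(seg$labels), dim(volume$voxels)))
  vs <- volume$voxel_size
  dims <- dim(volume$voxels)
  if (is.null(aquarium_id)) aquarium_id <- volume$aquarium_id
  lab <- seg$labels > 0L
  n_vox <- sum(lab)
  if (n_vox == 0L) {
    out <- data.frame(aquarium_id = aquarium_id, B_max_cm = 0, B_SA_cm2 = 0,
                      B_vol_cm3 = 0, n_components = 0L,
                      stringsAsFactors = FALSE)
    class(out) <- c("burrow_metrics", "data.frame")
    return(out)
  }
  idx <- which(lab)
  x <- (idx - 1L) %% dims[1] + 1L
  y <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  z <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  if (is.null(surface_z)) surface_z <- matrix(min(z), dims[1], dims[2])
  depth_vox <- pmax(0L, z - surface_z[cbind(x, y)])
  b_max <- max(depth_vox) * vs

  mesh_mask <- lab
  if (!include_openings) {
    # extend open burrows upward past the smoothing support, then drop
    # triangles above the local surface: removes the opening cap without
    # creating spurious wall area
    pad_up <- as.integer(ceiling(3 * mesh_sigma) + 1L)
    sz <- surface_z[cbind(x, y)]
    at_surface <- which(z == sz)
    for (i in at_surface) {
      zr <- max(1L, z[i] - pad_up):(z[i] - 1L)
      if (z[i] > 1L) mesh_mask[x[i], y[i], zr] <- TRUE
    }
  }
  m <- mask_mesh(mesh_mask, sigma = mesh_sigma)
  if (nrow(m$p1) == 0L) {
    b_sa <- 0
  } else if (include_openings) {
    b_sa <- sum(triangle_areas(m$p1, m$p2, m$p3)) * vs^2
  } else {
    cx <- pmin(pmax(round(m$centroid[, 1]), 1L), dims[1])
    cy <- pmin(pmax(round(m$centroid[, 2]), 1L), dims[2])
    keep <- m$centroid[, 3] >= (surface_z[cbind(cx, cy)] - 0.5)
    b_sa <- sum(triangle_areas(m$p1[keep, , drop = FALSE],
                               m$p2[keep, , drop = FALSE],
                               m$p3[keep, , drop = FALSE])) * vs^2
  }
  out <- data.frame(aquarium_id = aquarium_id, B_max_cm = b_max,
                    B_SA_cm2 = b_sa, B_vol_cm3 = n_vox * vs^3,
                    n_components = nrow(seg$components),
                    stringsAsFactors = FALSE)
  class(out) <- c("burrow_metrics", "data.frame")
  out
}

#' Full CT analysis of one volume
#'
#' Convenience wrapper: \code{\link{segment_burrows}} followed by
#' \code{\link{burrow_metrics}} with the estimated surface map.
#'
#' @inheritParams segment_burrows
#' @inheritParams burrow_metrics
#' @return See \code{\link{burrow_metrics}}.
#' @export
ct_analyse <- function(volume, threshold = "otsu", connectivity = 26L,
                       min_component_voxels = 27L, include_openings = FALSE) {
  s <- segment_burrows(volume, threshold, connectivity, min_component_voxels)
  burrow_metrics(s$segmentation, volume, surface_z = s$surface_z,
                 include_openings = include_openings)
}
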