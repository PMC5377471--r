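# Independent brute-force oracles used to validate the pipeline.

# Exhaustive flood fill (breadth-first) over a logical 3-D mask, independent
# of the igraph-backed implementation in the package.
flood_fill_oracle <- function(mask, seed, connectivity = 26L) {
  dims <- dim(mask)
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(abs(o)) > 0, , drop = FALSE]
  }
  seen <- array(FALSE, dims)
  if (!mask[seed[1], seed[2], seed[3]]) return(integer(0))
  seen[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, 1, 3)
  while (nrow(frontier) > 0) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
      sweep(frontier, 2, offs[i, ], `+`)
    }))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
          nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
          nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
    nxt <- nxt[ok, , drop = FALSE]
    if (nrow(nxt) == 0) break
    nxt <- unique(nxt)
    keep <- mask[nxt] & !seen[nxt]
    nxt <- nxt[keep, , drop = FALSE]
    if (nrow(nxt) == 0) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  sort(which(seen))
}

# one-line brute-force reworking statistics over a placed-particle depth list
brute_depth_stats <- function(depths) {
  c(L_med = median(depths), L_mean = mean(depths), L_max = max(depths))
}

# discrete capsule membership count: voxels within radius r of the vertical
# segment x = e[1], y = e[2], z in [z0, z1], restricted to z >= z_surface
capsule_count <- function(dims, e, z0, z1, r, z_surface) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  zc <- pmin(pmax(idx[, 3], z0), z1)
  d2 <- (idx[, 1] - e[1])^2 + (idx[, 2] - e[2])^2 + (idx[, 3] - zc)^2
  sum(d2 <= r^2 & idx[, 3] >= z_surface)
}

# tiny volume with dark voids on a bright background
make_test_volume <- function(dims, void_idx, voxel_size = 0.05,
                             dark = 20, bright = 200) {
  v <- array(bright, dims)
  v[void_idx] <- dark
  voxel_volume(v, voxel_size)
}
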