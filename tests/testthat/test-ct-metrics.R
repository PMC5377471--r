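# Burrow morphometrics: exact volume, mesh surface area, maximum depth.

test_that("a single labelled voxel has exactly voxel_size^3 volume", {
  v <- array(200, c(8, 8, 8)); v[4, 4, 4] <- 20
  vol <- voxel_volume(v, 0.1)
  seg <- grow_regions(vol, rbind(c(4, 4, 4)), threshold = 100)
  bm <- burrow_metrics(seg, vol, surface_z = matrix(1L, 8, 8))
  expect_equal(bm$B_vol_cm3, 0.001)
  expect_equal(bm$n_components, 1L)
})

test_that("B_vol is the exact voxel count times voxel_size^3", {
  g <- make_burrow_volume(species_archetype("u_tube"), c(44, 44, 60),
                          voxel_size = 0.06, noise_sd = 0, seed = 8)
  s <- segment_burrows(g$volume)
  bm <- burrow_metrics(s$segmentation, g$volume, s$surface_z)
  expect_equal(bm$B_vol_cm3, sum(s$segmentation$labels > 0) * 0.06^3)
  expect_equal(sum(s$segmentation$labels > 0),
               length(g$ground_truth$burrow_voxel_set))
})

test_that("carved cylinder volume and lateral+base area match the analytic oracle", {
  vs <- 0.0081; r <- 20; h <- 100
  dims <- c(52L, 52L, 112L)
  vox <- array(200, dims)
  in_disk <- outer((seq_len(dims[1]) - 26.5)^2,
                   (seq_len(dims[2]) - 26.5)^2, `+`) <= r^2
  zs <- 4L
  for (z in zs:(zs + h - 1L)) vox[, , z][in_disk] <- 20
  vol <- voxel_volume(vox, vs)
  seg <- grow_regions(vol, rbind(c(26, 26, 20)), threshold = 100)
  bm <- burrow_metrics(seg, vol, surface_z = matrix(zs, dims[1], dims[2]))
  expect_lt(abs(bm$B_vol_cm3 / (pi * r^2 * h * vs^3) - 1), 0.02)
  expect_lt(abs(bm$B_SA_cm2 / ((2 * pi * r * h + pi * r^2) * vs^2) - 1), 0.03)
  expect_equal(bm$B_max_cm, (h - 1) * vs)
  # including the opening cap adds about one disk of area
  bm_open <- burrow_metrics(seg, vol, surface_z = matrix(zs, dims[1], dims[2]),
                            include_openings = TRUE)
  expect_gt(bm_open$B_SA_cm2, bm$B_SA_cm2)
  expect_lt(abs((bm_open$B_SA_cm2 - bm$B_SA_cm2) / (pi * r^2 * vs^2) - 1),
            0.25)
})

test_that("mesh area of a carved sphere converges to 4 pi r^2", {
  r <- 15
  m <- array(FALSE, c(40, 40, 40))
  co <- as.matrix(expand.grid(x = 1:40, y = 1:40, z = 1:40))
  inside <- (co[, 1] - 20.5)^2 + (co[, 2] - 20.5)^2 + (co[, 3] - 20.5)^2 <= r^2
  m[co[inside, ]] <- TRUE
  msh <- bioturb:::mask_mesh(m, sigma = 1)
  area <- sum(bioturb:::triangle_areas(msh$p1, msh$p2, msh$p3))
  expect_lt(abs(area / (4 * pi * r^2) - 1), 0.03)
})

test_that("empty segmentation yields all-zero metrics", {
  v <- array(200, c(10, 10, 10))
  vol <- voxel_volume(v, 0.1)
  seg <- structure(list(labels = array(0L, c(10, 10, 10)),
                        components = data.frame(id = integer(0),
                                                voxel_count = integer(0)),
                        threshold = 100, connectivity = 26L),
                   class = "burrow_segmentation")
  bm <- burrow_metrics(seg, vol)
  expect_equal(bm$B_vol_cm3, 0)
  expect_equal(bm$B_SA_cm2, 0)
  expect_equal(bm$B_max_cm, 0)
  expect_equal(bm$n_components, 0L)
})

test_that("gallery burrows reach deeper than U-tubes in pipeline metrics", {
  d <- sapply(c("gallery_diffuser", "u_tube"), function(nm) {
    g <- make_burrow_volume(species_archetype(nm), c(56, 56, 176),
                            voxel_size = 0.05, noise_sd = 5, seed = 19)
    ct_analyse(g$volume)$B_max_cm
  })
  expect_gt(d["gallery_diffuser"], d["u_tube"])
})

test_that("B_max agrees with the ground-truth maximum void depth", {
  for (nm in c("i_shaft", "u_tube")) {
    g <- make_burrow_volume(species_archetype(nm), c(48, 48, 80),
                            voxel_size = 0.05, noise_sd = 0, seed = 29)
    s <- segment_burrows(g$volume)
    bm <- burrow_metrics(s$segmentation, g$volume, s$surface_z)
    expect_lt(abs(bm$B_max_cm - g$ground_truth$max_void_depth_cm), 0.05 + 1e-9)
  }
})
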