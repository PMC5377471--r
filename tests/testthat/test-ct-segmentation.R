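# Seed-point region growing, auto-seeding, and their flood-fill oracle.

test_that("an isolated dark cube grows to exactly its 27 voxels", {
  v <- array(200, c(10, 10, 10))
  v[4:6, 4:6, 4:6] <- 20
  seg <- grow_regions(voxel_volume(v, 0.1), rbind(c(5, 5, 5)), threshold = 100)
  expect_equal(seg$components$voxel_count, 27L)
  expect_equal(sum(seg$labels > 0), 27L)
})

test_that("noise-free synthetic shaft segmentation equals ground truth exactly", {
  g <- make_burrow_volume(species_archetype("i_shaft"), c(48, 48, 80),
                          voxel_size = 0.05, noise_sd = 0, seed = 3)
  s <- segment_burrows(g$volume)
  expect_identical(sort(which(s$segmentation$labels > 0)),
                   g$ground_truth$burrow_voxel_set)
})

test_that("region growing equals the exhaustive flood-fill oracle", {
  # random volumes up to 32^3, both connectivities (the acceptance suite
  # extends this to 100 volumes)
  for (s in 1:12) {
    set.seed(s)
    dims <- sample(6:20, 3, replace = TRUE)
    if (s <= 2) dims <- c(32, 32, 32)
    v <- array(sample(c(20, 200), prod(dims), replace = TRUE,
                      prob = c(0.35, 0.65)), dims)
    dark <- which(v <= 100)
    if (!length(dark)) next
    lin <- dark[sample.int(length(dark), 1)]
    seed <- c((lin - 1) %% dims[1] + 1,
              ((lin - 1) %/% dims[1]) %% dims[2] + 1,
              (lin - 1) %/% (dims[1] * dims[2]) + 1)
    for (conn in c(6L, 26L)) {
      seg <- grow_regions(voxel_volume(v, 0.05), rbind(seed),
                          threshold = 100, connectivity = conn)
      got <- sort(which(seg$labels > 0))
      want <- flood_fill_oracle(v <= 100, seed, conn)
      expect_identical(got, want)
    }
  }
})

test_that("26-connectivity growth contains 6-connectivity growth", {
  set.seed(99)
  dims <- c(18, 18, 18)
  v <- array(sample(c(20, 200), prod(dims), replace = TRUE), dims)
  dark <- which(v <= 100)
  lin <- dark[1]
  seed <- c((lin - 1) %% 18 + 1, ((lin - 1) %/% 18) %% 18 + 1,
            (lin - 1) %/% 324 + 1)
  s6 <- grow_regions(voxel_volume(v, 0.05), rbind(seed), 100, 6L)
  s26 <- grow_regions(voxel_volume(v, 0.05), rbind(seed), 100, 26L)
  expect_true(all(which(s6$labels > 0) %in% which(s26$labels > 0)))
})

test_that("raising the threshold never shrinks a component", {
  g <- make_burrow_volume(species_archetype("u_tube"), c(40, 40, 60),
                          voxel_size = 0.06, noise_sd = 15, seed = 21)
  s <- segment_burrows(g$volume, threshold = 90)
  if (nrow(s$seeds) > 0) {
    lo <- grow_regions(g$volume, s$seeds, threshold = 90)
    hi <- grow_regions(g$volume, s$seeds, threshold = 120)
    expect_true(all(which(lo$labels > 0) %in% which(hi$labels > 0)))
  } else {
    fail("no seeds found at threshold 90")
  }
})

test_that("invalid seeds produce informative errors and merged seeds one label", {
  v <- array(200, c(10, 10, 10)); v[4:6, 4:6, 4:6] <- 20
  vol <- voxel_volume(v, 0.1)
  expect_error(grow_regions(vol, rbind(c(1, 1, 1)), threshold = 100),
               "gray 200 above threshold")
  expect_error(grow_regions(vol, rbind(c(50, 1, 1)), threshold = 100),
               "outside")
  expect_error(grow_regions(vol, matrix(numeric(0), 0, 3), threshold = 100),
               "empty seed")
  both <- grow_regions(vol, rbind(c(4, 4, 4), c(6, 6, 6)), threshold = 100)
  expect_equal(nrow(both$components), 1L)
  expect_equal(max(both$labels), 1L)
})

test_that("auto seeding finds one seed per structure and skips small/absent ones", {
  # all-bright volume: nothing to seed
  vol <- voxel_volume(array(200, c(12, 12, 12)), 0.1)
  expect_equal(nrow(auto_seed(vol, threshold = 100,
                              surface_z = matrix(1L, 12, 12))), 0L)
  # two separate carved tubes
  v <- array(200, c(20, 20, 30))
  v[4:6, 4:6, 5:25] <- 20
  v[14:16, 14:16, 5:25] <- 20
  seeds <- auto_seed(voxel_volume(v, 0.05), threshold = 100,
                     min_component_voxels = 50,
                     surface_z = matrix(3L, 20, 20))
  expect_equal(nrow(seeds), 2L)
  # generated shafts: one seed per ground-truth structure
  g <- make_burrow_volume(species_archetype("i_shaft"), c(56, 56, 80),
                          voxel_size = 0.05, noise_sd = 0, seed = 15)
  s <- segment_burrows(g$volume, min_component_voxels = 50)
  expect_equal(nrow(s$seeds), g$ground_truth$n_structures)
})
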