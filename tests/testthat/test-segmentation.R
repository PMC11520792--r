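block_mask <- function(dims, lo, hi, spacing = 0.2) {
  a <- array(FALSE, dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(a, rep(spacing, 3), c(0, 0, 0))
}

test_that("thresholding is strict and counts voxels exactly", {
  z <- voxel_volume(array(0, c(20, 20, 20)))
  expect_identical(sum(threshold_volume(z)$values), 0L)
  blk <- array(0, c(20, 20, 20))
  blk[6:15, 6:15, 6:15] <- 2000
  expect_identical(sum(threshold_volume(voxel_volume(blk))$values), 1000L)
  at_thr <- voxel_volume(array(1600, c(5, 5, 5)))
  expect_identical(sum(threshold_volume(at_thr)$values), 0L)
})

test_that("lowering the threshold never shrinks the voxel set", {
  set.seed(9)
  v <- voxel_volume(array(runif(8000, 0, 3000), c(20, 20, 20)))
  m_hi <- threshold_volume(v, segmentation_config(hu_threshold = 2000))
  m_lo <- threshold_volume(v, segmentation_config(hu_threshold = 1200))
  expect_true(all(m_lo$values[m_hi$values]))
})

test_that("cavity filling adds exactly the enclosed hollow", {
  m <- block_mask(c(15, 15, 15), c(3, 3, 3), c(13, 13, 13))
  hollow <- m
  hollow$values[7:9, 7:9, 7:9] <- FALSE
  filled <- fill_internal_cavities(hollow)
  expect_identical(sum(filled$values) - sum(hollow$values), 27L)
  expect_identical(filled$values, m$values)
})

test_that("cavity filling is extensive, idempotent and a no-op on solids", {
  solid <- block_mask(c(12, 12, 12), c(3, 3, 3), c(10, 10, 10))
  expect_identical(fill_internal_cavities(solid)$values, solid$values)
  # extensive + idempotent on a mask with a cavity and a notch
  m <- solid
  m$values[5:7, 5:7, 5:7] <- FALSE
  f1 <- fill_internal_cavities(m)
  expect_true(all(f1$values[m$values]))
  f2 <- fill_internal_cavities(f1)
  expect_identical(f2$values, f1$values)
})

test_that("a narrow-mouthed hollow is sealed by the closing step", {
  # hollow cylinder along z whose cavity opens through a narrow neck at
  # the top; neck diameter ~5 voxels < 2 * closing radius 3, so the
  # closing seals the mouth and the interior fills
  dims <- c(21, 21, 26)
  a <- array(FALSE, dims)
  cx <- 11; cy <- 11
  for (i in 1:21) for (j in 1:21) {
    r <- sqrt((i - cx)^2 + (j - cy)^2)
    if (r <= 7) a[i, j, 4:22] <- TRUE
    if (r <= 4) a[i, j, 7:16] <- FALSE      # cavity
    if (r <= 2) a[i, j, 17:22] <- FALSE     # narrow neck, open at z=22
  }
  m <- binary_mask(a, rep(0.2, 3), c(0, 0, 0))
  filled <- fill_internal_cavities(m, closing_radius_voxels = 3)
  # deep cavity voxels (well below the neck) must be foreground now
  expect_true(all(filled$values[cx + (-2:2), cy + (-2:2), 8:12]))
  expect_true(all(filled$values[m$values]))
})

test_that("largest_component keeps the biggest blob with a stable tie-break", {
  solo <- block_mask(c(12, 12, 12), c(3, 3, 3), c(10, 10, 10))
  expect_identical(largest_component(solo)$values, solo$values)
  m <- block_mask(c(30, 12, 12), c(2, 2, 2), c(11, 11, 11))
  m$values[25:26, 5:6, 5:6] <- TRUE       # 8-voxel speck
  keep <- largest_component(m)
  expect_identical(sum(keep$values), 1000L)
  expect_false(any(keep$values[25:26, , ]))
  # two equal blocks: the one containing the lower linear index survives
  m2 <- binary_mask(array(FALSE, c(20, 8, 8)), rep(0.2, 3), c(0, 0, 0))
  m2$values[2:4, 2:4, 2:4] <- TRUE
  m2$values[12:14, 2:4, 2:4] <- TRUE
  k2 <- largest_component(m2)
  expect_true(any(k2$values[2:4, , ]))
  expect_false(any(k2$values[12:14, , ]))
  expect_error(largest_component(binary_mask(array(FALSE, c(4, 4, 4)),
                                             rep(1, 3), c(0, 0, 0))),
               "no foreground")
})

test_that("extract_surface refuses boundary-touching foreground", {
  m <- block_mask(c(10, 10, 10), c(1, 3, 3), c(5, 7, 7))
  expect_error(extract_surface(m), "boundary")
})

test_that("a single voxel yields a closed surface of about one voxel volume", {
  m <- binary_mask(array(FALSE, c(9, 9, 9)), rep(0.2, 3), c(0, 0, 0))
  m$values[5, 5, 5] <- TRUE
  s <- extract_surface(m, smooth_sigma_voxels = 0)
  expect_true(mesh_is_closed(s))
  expect_gt(mesh_area(s), 0)
  expect_lt(abs(mesh_volume(s) / 0.2^3 - 1), 0.6)
})

test_that("segmenting a voxelized sphere reproduces its area and volume", {
  s <- sphere_fixture(5, 0.12)
  vol <- voxelize(s, spacing = 0.2)
  mesh <- segment_volume(vol)
  expect_true(mesh_is_closed(mesh))
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 25) - 1), 0.02)
  expect_lt(abs(mesh_volume(mesh) / (4 / 3 * pi * 125) - 1), 0.02)
})

test_that("noise-free reconstruction stays within one voxel diagonal", {
  ph <- phantom_fixture("premolar")
  mesh <- segmented_fixture("premolar")
  bound <- 0.2 * sqrt(3)
  expect_lt(max(euclidean_field(mesh, ph$mesh)$values), bound)
  expect_lt(max(euclidean_field(ph$mesh, mesh)$values), bound)
})

test_that("canal filling controls the reconstruction topology", {
  ph <- phantom_fixture("premolar")
  vol <- voxelize(ph$mesh, spacing = 0.2, canals = canal_paths(ph$spec))
  with_fill <- segment_volume(vol)
  expect_identical(mesh_shell_count(with_fill), 1L)
  expect_identical(euler_characteristic(with_fill), 2L)
  without <- segment_volume(vol, segmentation_config(fill_canals = FALSE))
  expect_true(mesh_shell_count(without) > 1L ||
                euler_characteristic(without) != 2L)
})
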