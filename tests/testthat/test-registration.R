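test_that("initial_align never worsens identical meshes and recovers a shift", {
  m <- phantom_fixture("premolar")$mesh
  grid <- toothrep:::.cpp_grid_build(m$vertices, m$triangles)
  before <- sqrt(mean(toothrep:::.cpp_grid_closest(grid, m$vertices)$distance^2))
  tf <- initial_align(m, m)
  after <- sqrt(mean(toothrep:::.cpp_grid_closest(
    grid, apply_transform(tf, m$vertices))$distance^2))
  expect_lte(after, before + 1e-9)

  # translated sphere: centroid difference recovered, rotation irrelevant
  s <- sphere_fixture(4, 0.3)
  s2 <- s
  s2$vertices <- sweep(s2$vertices, 2, c(3, 0, 0), "+")
  expect_message(tf2 <- initial_align(s2, s), "isotropic")
  expect_equal(tf2$translation, c(-3, 0, 0), tolerance = 0.01)
})

test_that("a large rotation about the long axis is captured coarsely", {
  m <- phantom_fixture("canine")$mesh
  gt <- rigid_transform(rotation_about(c(0, 0, 1), 170), c(2, -1, 3))
  src <- transform_mesh(m, gt)
  tf <- initial_align(src, m)
  grid <- toothrep:::.cpp_grid_build(m$vertices, m$triangles)
  rms <- sqrt(mean(toothrep:::.cpp_grid_closest(
    grid, apply_transform(tf, src$vertices))$distance^2))
  expect_lt(rms, 1)
})

test_that("ICP on identical meshes returns the identity", {
  m <- phantom_fixture("premolar")$mesh
  reg <- icp_register(m, m, icp_config(subsample_count = 1500L))
  expect_lt(rotation_angle(reg$transform), 1e-6)
  expect_lt(max(abs(reg$transform$translation)), 1e-6)
  expect_lt(tail(reg$rms_history, 1), 1e-9)
})

test_that("ICP recovers seeded random rigid transforms exactly", {
  for (kind in c("premolar", "molar")) {
    m <- phantom_fixture(kind)$mesh
    set.seed(101)
    for (i in 1:4) {
      gt <- rigid_transform(rotation_about(rnorm(3), runif(1, 2, 20)),
                            runif(3, -5, 5))
      src <- transform_mesh(m, gt)
      cfg <- icp_config(subsample_count = 1500L, seed = i)
      reg <- icp_register(src, m, cfg, init = initial_align(src, m, seed = i))
      err <- compose_transforms(reg$transform, gt)
      expect_lt(rotation_angle(err), 0.1)
      expect_lt(sqrt(sum((err$translation +
        (err$rotation - diag(3)) %*% colMeans(m$vertices))^2)), 0.02)
      expect_true(all(diff(reg$rms_history) <= 1e-9))
    }
  }
})

test_that("milling noise bounds the ICP residual at the noise floor", {
  m <- phantom_fixture("canine")$mesh
  gt <- rigid_transform(rotation_about(c(1, 2, 0.5), 12), c(2, 1, -3))
  noisy <- simulate_replica(m, 0.05, seed = 3, smooth_iterations = 0)
  src <- transform_mesh(noisy, gt)
  reg <- icp_register(src, m, icp_config(subsample_count = 2000L, seed = 3),
                      init = initial_align(src, m, seed = 3))
  expect_lt(tail(reg$rms_history, 1), 3 * 0.05)
})

test_that("merging a mesh with itself welds back to the original", {
  m <- sphere_fixture(4, 0.3)
  merged <- merge_half_scans(m, m)
  expect_identical(nrow(merged$vertices), nrow(m$vertices))
})

test_that("displaced half scans merge onto the ground truth", {
  m <- phantom_fixture("premolar")$mesh
  # split at the crown base (the crown-scan / root-scan protocol) with a
  # 2 mm overlap band; the elliptical crown cross-section in the band
  # constrains all six degrees of freedom
  zs <- matrix(m$vertices[m$triangles, 3], ncol = 3)
  z0 <- -1
  top <- submesh(m, rowMeans(zs) > z0 - 1)
  bottom <- submesh(m, rowMeans(zs) < z0 + 1)
  shift <- rigid_transform(rotation_about(c(0, 1, 0), 4), c(0.8, -0.5, 0.4))
  bottom_moved <- transform_mesh(bottom, shift)
  merged <- merge_half_scans(top, bottom_moved,
                             icp_config(trim_fraction = 0.8,
                                        subsample_count = 3000L))
  dev <- euclidean_field(merged, m)
  expect_lt(max(dev$values), 0.05)
})

test_that("non-overlapping scans are refused", {
  a <- sphere_fixture(5, 0.4)
  b <- sphere_fixture(2, 0.4)
  expect_error(merge_half_scans(a, b), "overlap")
})
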