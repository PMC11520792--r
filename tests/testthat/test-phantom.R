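test_that("phantom generation is deterministic and kind-correct", {
  a <- make_phantom("premolar", seed = 1)
  b <- make_phantom("premolar", seed = 1)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$triangles, b$mesh$triangles)
  expect_identical(length(a$spec$root_specs), 1L)
  expect_identical(length(make_phantom("canine", 1)$spec$root_specs), 1L)
  expect_gte(length(phantom_fixture("molar")$spec$root_specs), 2L)
  expect_error(make_phantom("incisor", 1))
})

test_that("the seed does not alter the deterministic geometry", {
  a <- make_phantom("canine", seed = 7)
  b <- make_phantom("canine", seed = 8)
  expect_identical(nrow(a$mesh$triangles), nrow(b$mesh$triangles))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
})

test_that("phantom meshes are closed genus-0 surfaces", {
  for (kind in c("premolar", "canine", "molar")) {
    m <- phantom_fixture(kind)$mesh
    expect_true(mesh_is_closed(m))
    expect_identical(euler_characteristic(m), 2L)
    expect_identical(mesh_shell_count(m), 1L)
  }
})

test_that("molar cross-section below the furcation has two loops", {
  m <- phantom_fixture("molar")$mesh
  # below the furcation the two roots are disjoint in cross-section
  expect_gte(oracle_slice_loops(m, -8), 2L)
  # through the crown there is a single loop
  expect_identical(oracle_slice_loops(m, 1), 1L)
})

test_that("voxel membership matches the analytic sphere and the R parity oracle", {
  s <- sphere_fixture(5, 0.12)
  vol <- voxelize(s, spacing = 0.2)
  inside <- vol$values > 1600
  ax <- grid_axes_of(vol)
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  truth <- rowSums(g^2) <= 25
  # the mesh is a fine discretisation of the sphere: centre classification
  # may differ only within its chordal tolerance of the exact surface
  mismatch <- sum(inside != truth)
  near <- abs(sqrt(rowSums(g^2)) - 5) < 0.01
  expect_lte(mismatch, sum(near))
  expect_lt(mismatch / sum(truth), 1e-3)

  # exact agreement with a plain-R parity oracle on a coarse cube mesh
  cube <- cube_fixture()
  set.seed(3)
  P <- matrix(runif(90, -0.3, 1.3), ncol = 3)
  grid <- toothrep:::.cpp_grid_build(cube$vertices, cube$triangles)
  got <- toothrep:::.cpp_points_in_mesh(grid, P)
  expect_identical(as.vector(got), as.vector(oracle_in_mesh(cube, P)))
})

test_that("voxelization is deterministic and threshold-separable", {
  s <- sphere_fixture(3, 0.3)
  v1 <- voxelize(s, spacing = 0.25, noise_sd = 20, seed = 5)
  v2 <- voxelize(s, spacing = 0.25, noise_sd = 20, seed = 5)
  expect_identical(v1$values, v2$values)
  v3 <- voxelize(s, spacing = 0.25, noise_sd = 20, seed = 6)
  expect_false(identical(v1$values, v3$values))
  # blur = noise = 0: any threshold strictly between the HU levels
  # recovers exactly the inside-mesh voxel set
  v0 <- voxelize(s, spacing = 0.25)
  m800 <- v0$values > 800
  m1900 <- v0$values > 1900
  expect_identical(m800, m1900)
})

test_that("voxelize rejects an open mesh and pads the surface", {
  cube <- cube_fixture()
  open_mesh <- surface_mesh(cube$vertices, cube$triangles[-1, ])
  expect_error(voxelize(open_mesh), "closed")
  v <- voxelize(cube, spacing = 0.25)
  d <- dim(v$values)
  expect_false(any(v$values[c(1, d[1]), , ] > 1600))
  expect_false(any(v$values[, , c(1, d[3])] > 1600))
})

test_that("canal carving lowers HU inside the canal channel", {
  ph <- phantom_fixture("premolar")
  vol <- voxelize(ph$mesh, spacing = 0.2, canals = canal_paths(ph$spec))
  cp <- canal_paths(ph$spec)[[1]]
  mid <- (cp$from + cp$to) / 2
  ax <- grid_axes_of(vol)
  idx <- vapply(1:3, function(a) which.min(abs(ax[[a]] - mid[a])), 1L)
  expect_equal(vol$values[idx[1], idx[2], idx[3]], 300)
})

test_that("deform_bump is local, tapered and exact at its centre", {
  s <- sphere_fixture(5, 0.15)
  expect_identical(deform_bump(s, c(0, 0, 5), 2, 0), s)
  b <- deform_bump(s, c(0, 0, 5), 2, 0.8)
  d <- sqrt(colSums((t(s$vertices) - c(0, 0, 5))^2))
  outside <- d >= 2
  expect_identical(b$vertices[outside, ], s$vertices[outside, ])
  # a +0.8 mm polar bump raises the maximum radius to ~5.8
  expect_equal(max(sqrt(rowSums(b$vertices^2))), 5.8, tolerance = 0.02)
  # displaced vertex nearest the centre moves by the full amplitude
  i <- which.min(d)
  moved <- sqrt(sum((b$vertices[i, ] - s$vertices[i, ])^2))
  expect_equal(moved, 0.8 * 0.5 * (1 + cos(pi * d[i] / 2)), tolerance = 1e-9)
})

test_that("simulate_replica displacement statistics match the seeded noise", {
  s <- sphere_fixture(5, 0.15)
  expect_identical(simulate_replica(s, 0), s)
  r1 <- simulate_replica(s, 0.05, seed = 2, smooth_iterations = 0)
  r2 <- simulate_replica(s, 0.05, seed = 2, smooth_iterations = 0)
  expect_identical(r1$vertices, r2$vertices)
  disp <- sqrt(rowSums((r1$vertices - s$vertices)^2))
  n <- length(disp)
  # |N(0, sd)| has mean sd*sqrt(2/pi); allow 3 standard errors
  expect_lt(abs(mean(disp) - 0.05 * sqrt(2 / pi)),
            3 * 0.05 * sqrt(1 - 2 / pi) / sqrt(n))
})
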