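test_that("mesh container validates its invariants", {
  expect_error(surface_mesh(matrix(1, 2, 2), matrix(1L, 1, 3)), "3 columns")
  expect_error(surface_mesh(matrix(c(1, NA, 1), 1, 3), matrix(1L, 1, 3)),
               "finite")
  expect_error(surface_mesh(matrix(rnorm(9), 3, 3),
                            matrix(c(1L, 2L, 4L), 1, 3)), "out of range")
})

test_that("area, volume, Euler characteristic and shells are exact on a cube", {
  cube <- cube_fixture()
  expect_equal(mesh_area(cube), 6)
  expect_equal(mesh_volume(cube), 1)
  expect_true(mesh_is_closed(cube))
  expect_identical(euler_characteristic(cube), 2L)
  expect_identical(mesh_shell_count(cube), 1L)
  # two disjoint cubes: two shells, Euler characteristic 4
  shifted <- cube
  shifted$vertices <- shifted$vertices + 5
  two <- surface_mesh(rbind(cube$vertices, shifted$vertices),
                      rbind(cube$triangles, shifted$triangles + 8L))
  expect_identical(mesh_shell_count(two), 2L)
  expect_identical(euler_characteristic(two), 4L)
})

test_that("isosurface of a sphere SDF is watertight and metrically accurate", {
  m <- sphere_fixture(5, 0.15)
  expect_true(mesh_is_closed(m))
  expect_identical(euler_characteristic(m), 2L)
  expect_lt(abs(mesh_area(m) / (4 * pi * 25) - 1), 0.005)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 125) - 1), 0.005)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 5)), 0.01)
  # outward orientation: signed volume positive
  expect_gt(mesh_volume(m, signed = TRUE), 0)
})

test_that("vertex normals of a sphere point radially outward", {
  m <- sphere_fixture(4, 0.3)
  n <- vertex_normals(m)
  radial <- m$vertices / sqrt(rowSums(m$vertices^2))
  dots <- rowSums(n * radial)
  expect_gt(min(dots), 0.9)
})

test_that("welding merges duplicates and drops collapsed triangles", {
  cube <- cube_fixture()
  dup <- surface_mesh(rbind(cube$vertices, cube$vertices),
                      rbind(cube$triangles, cube$triangles + 8L))
  w <- weld_vertices(dup)
  expect_identical(nrow(w$vertices), 8L)
})

test_that("STL write/read round-trips a mesh through both encodings", {
  m <- sphere_fixture(3, 0.5)
  tmp <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, tmp)
  back <- read_stl(tmp)
  expect_identical(nrow(back$triangles), nrow(m$triangles))
  expect_equal(mesh_area(back), mesh_area(m), tolerance = 1e-5)
  expect_equal(sort(back$vertices[, 1]), sort(m$vertices[, 1]),
               tolerance = 1e-5)
  # ASCII encoding of the same mesh welds to the identical mesh
  tmp2 <- withr::local_tempfile(fileext = ".stl")
  co <- m$vertices[t(m$triangles), ]
  lines <- c("solid ascii")
  for (i in seq_len(nrow(m$triangles))) {
    a <- co[3 * i - 2, ]; b <- co[3 * i - 1, ]; cc <- co[3 * i, ]
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %.9f %.9f %.9f", a[1], a[2], a[3]),
               sprintf("   vertex %.9f %.9f %.9f", b[1], b[2], b[3]),
               sprintf("   vertex %.9f %.9f %.9f", cc[1], cc[2], cc[3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid"), tmp2)
  back2 <- read_stl(tmp2)
  expect_identical(nrow(back2$triangles), nrow(back$triangles))
  expect_identical(nrow(back2$vertices), nrow(back$vertices))
})

test_that("reading an empty or truncated STL fails loudly", {
  tmp <- withr::local_tempfile(fileext = ".stl")
  m <- cube_fixture()
  write_stl(m, tmp)
  raw <- readBin(tmp, "raw", n = file.info(tmp)$size)
  # zero triangle count
  zero <- raw
  zero[85:88] <- as.raw(0)
  writeBin(zero[1:88], tmp)
  expect_error(read_stl(tmp), "empty|truncated")
  # truncated body
  writeBin(raw[1:120], tmp)
  expect_error(read_stl(tmp), "truncated")
})

test_that("Taubin smoothing keeps a sphere close to its radius", {
  m <- sphere_fixture(4, 0.3)
  s <- smooth_mesh(m, iterations = 5)
  r <- sqrt(rowSums(s$vertices^2))
  expect_lt(abs(mean(r) - 4), 0.05)
})
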