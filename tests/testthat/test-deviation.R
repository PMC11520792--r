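test_that("euclidean_field equals the brute-force all-triangle oracle", {
  for (seed in c(21, 22, 23)) {
    basis <- blob_fixture(seed)
    other <- blob_fixture(seed + 50)
    expect_lte(nrow(other$triangles), 500)
    f <- euclidean_field(basis, other)
    oracle <- oracle_closest(other, basis$vertices)
    expect_lt(max(abs(f$values - oracle)), 1e-9)
  }
})

test_that("distance to the same mesh is zero", {
  m <- sphere_fixture(3, 0.4)
  expect_equal(max(euclidean_field(m, m)$values), 0)
  no <- normal_field(m, m)
  expect_equal(max(abs(no$values)), 0)
  expect_identical(sum(no$missing), 0L)
})

test_that("concentric spheres give the analytic gap with the stated sign", {
  inner <- sphere_fixture(5, 0.15)
  outer <- sphere_fixture(5.5, 0.15)
  eu <- euclidean_field(inner, outer)
  expect_lt(max(abs(eu$values - 0.5)), 0.01)
  # field on the smaller mesh, larger mesh outside: positive sign
  no <- normal_field(inner, outer)
  expect_identical(sum(no$missing), 0L)
  expect_lt(max(abs(no$values - 0.5)), 0.01)
  # swapped: larger basis, other inside: negative
  no2 <- normal_field(outer, inner)
  expect_lt(max(abs(no2$values + 0.5)), 0.01)
})

test_that("euclidean never exceeds the normal magnitude where a hit exists", {
  basis <- segmented_fixture("premolar")
  other <- phantom_fixture("premolar")$mesh
  eu <- euclidean_field(basis, other)
  no <- normal_field(basis, other)
  ok <- !no$missing
  expect_gt(sum(ok), 0.95 * length(ok))
  expect_true(all(eu$values[ok] <= abs(no$values[ok]) + 1e-9))
})

test_that("inflating the other mesh shifts the signed field by the offset", {
  m <- sphere_fixture(4, 0.25)
  n <- vertex_normals(m)
  inflated <- m
  inflated$vertices <- m$vertices + 0.3 * n
  no <- normal_field(m, inflated)
  expect_lt(max(abs(no$values[!no$missing] - 0.3)), 0.02)
})

test_that("an unoriented basis mesh is rejected for normal distances", {
  m <- sphere_fixture(3, 0.5)
  broken <- surface_mesh(m$vertices, m$triangles[-1, ])
  expect_error(normal_field(broken, m), "closed|orient")
})

test_that("summaries match hand arithmetic and a naive recomputation", {
  f <- distance_field(c(0, 0, 0), "euclidean")
  s <- summarize_field(f)
  expect_identical(c(s$min, s$mean, s$median, s$max), c(0, 0, 0, 0))

  g <- distance_field(c(-1, 0, 3), "normal")
  sg <- summarize_field(g)
  expect_equal(sg$mean, 2 / 3)
  expect_equal(sg$abs_mean, 4 / 3)
  expect_identical(sg$median, 0)
  expect_identical(sg$min, -1)
  expect_identical(sg$max, 3)

  set.seed(31)
  vals <- rnorm(101)
  sf <- summarize_field(distance_field(vals, "normal"))
  o <- oracle_summary(vals)
  expect_equal(sf$min, o$min)
  expect_equal(sf$max, o$max)
  expect_equal(sf$mean, o$mean)
  expect_equal(sf$median, o$median)
  # permutation invariance; even count uses the central-pair mean
  sf2 <- summarize_field(distance_field(sample(vals), "normal"))
  expect_equal(sf, sf2)
  se <- summarize_field(distance_field(c(4, 1, 3, 2), "euclidean"))
  expect_equal(se$median, 2.5)

  allmiss <- distance_field(c(NA_real_, NA_real_), "normal")
  expect_error(summarize_field(allmiss), "missing")
})

test_that("missing vertices are excluded from summaries and counted", {
  f <- distance_field(c(1, NA, 3, NA), "normal")
  s <- summarize_field(f)
  expect_identical(s$n_valid, 2L)
  expect_identical(s$n_missing, 2L)
  expect_equal(s$mean, 2)
})

test_that("comparing a rigidly moved copy of a mesh yields ~zero deviation", {
  m <- segmented_fixture("premolar")
  moved <- transform_mesh(m, rigid_transform(rotation_about(c(1, 0.3, 2), 15),
                                             c(4, -2, 1)))
  cmp <- compare_models(m, moved, "model",
                        icp_config(subsample_count = 1500L))
  expect_lt(cmp$euclidean_stats$max, 1e-3)
  expect_lt(max(abs(c(cmp$normal_stats$min, cmp$normal_stats$max))), 2e-3)
})

test_that("normal sign encodes which model the natural tooth exceeds", {
  # natural = larger sphere; model = smaller sphere
  natural <- sphere_fixture(5.5, 0.15)
  model <- sphere_fixture(5, 0.15)
  cm <- compare_models(natural, model, "model",
                       icp_config(subsample_count = 1000L))
  expect_gt(cm$normal_stats$mean, 0.45)     # natural bigger -> positive
  cm2 <- compare_models(natural, model, "natural",
                        icp_config(subsample_count = 1000L))
  expect_gt(cm2$normal_stats$mean, 0.45)    # same sign on the other basis
})
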