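# a reduced configuration keeps the full-pipeline tests quick: one tooth,
# coarser ground truth, no renders
light_config <- function(out_dir = NULL, seed = 1) {
  pipeline_config(tooth_kinds = "premolar", seed = seed,
                  phantom_resolution = 0.25,
                  icp = icp_config(subsample_count = 1500L),
                  out_dir = out_dir, write_meshes = TRUE)
}

test_that("run_study produces coherent reports and artifacts", {
  out <- withr::local_tempdir()
  res <- run_study(light_config(out_dir = out))
  expect_identical(length(res$reports), 2L)
  expect_identical(nrow(res$table), 4L)
  expect_identical(res$errors, list())
  # stats are internally consistent
  for (r in res$reports) {
    expect_lte(r$euclidean_stats$min, r$euclidean_stats$median)
    expect_lte(r$euclidean_stats$median, r$euclidean_stats$max)
    expect_gte(r$normal_stats$abs_mean, abs(r$normal_stats$mean))
  }
  # every intermediate artifact is written and individually reloadable
  base <- file.path(out, "premolar")
  expect_true(file.exists(file.path(out, "deviation_table.csv")))
  vol <- read_volume(file.path(base, "cbct_volume.json"))
  expect_s3_class(vol, "voxel_volume")
  cb <- read_stl(file.path(base, "cbct_model.stl"))
  expect_true(nrow(cb$vertices) > 1000)
  tf <- read_transform(file.path(base, "cbct_transform.json"))
  expect_s3_class(tf, "rigid_transform")
  f <- read.csv(file.path(base, "cbct_euclidean.csv"))
  expect_identical(names(f), c("vertex_index", "x_mm", "y_mm", "z_mm",
                               "value_mm", "missing"))
})

test_that("identical config and seed reproduce byte-identical reports", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_study(light_config(out_dir = out1, seed = 7))
  run_study(light_config(out_dir = out2, seed = 7))
  for (f in c("deviation_table.csv", "premolar/cbct_euclidean.csv",
              "premolar/replica_normal.csv")) {
    h1 <- readBin(file.path(out1, f), "raw", file.info(file.path(out1, f))$size)
    h2 <- readBin(file.path(out2, f), "raw", file.info(file.path(out2, f))$size)
    expect_identical(h1, h2)
  }
  # a different seed changes the stochastic stages
  out3 <- withr::local_tempdir()
  run_study(light_config(out_dir = out3, seed = 8))
  t1 <- readLines(file.path(out1, "deviation_table.csv"))
  t3 <- readLines(file.path(out3, "deviation_table.csv"))
  expect_false(identical(t1, t3))
})

test_that("the injected defect dominates the deviation map", {
  res <- run_study(light_config(seed = 2))
  d <- res$details$premolar
  maxima <- c(max(d$cmp_cbct$euclidean$values),
              max(d$cmp_repl$euclidean$values))
  best <- which.max(maxima)
  cmp <- if (best == 1) d$cmp_cbct else d$cmp_repl
  i <- which.max(cmp$euclidean$values)
  dist_to_bump <- sqrt(sum((cmp$basis$vertices[i, ] - d$bump$center)^2))
  expect_lt(dist_to_bump, d$bump$radius)
  expect_lt(abs(max(maxima) - abs(d$bump$amplitude)), 0.2)
})
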