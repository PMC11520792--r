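test_that("rigid transforms compose, invert and validate", {
  tf <- rigid_transform(rotation_about(c(0, 0, 1), 30), c(1, -2, 0.5))
  inv <- invert_transform(tf)
  id <- compose_transforms(inv, tf)
  expect_lt(rotation_angle(id), 1e-10)
  expect_lt(max(abs(id$translation)), 1e-10)
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "proper")
  expect_equal(rotation_angle(tf), 30, tolerance = 1e-10)
})

test_that("transform JSON serialization round-trips", {
  tf <- rigid_transform(rotation_about(c(1, 2, 3), 47), c(0.1, 20, -3))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, tmp)
  back <- read_transform(tmp)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tf$translation, tolerance = 1e-12)
})

test_that("best_rigid recovers an exact constructed transform", {
  set.seed(11)
  s <- matrix(rnorm(60), ncol = 3)
  # identity pairing
  id <- best_rigid(s, s)
  expect_lt(rotation_angle(id), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  # constructed rotation + translation
  R <- rotation_about(c(0, 0, 1), 30)
  tvec <- c(1, -2, 0.5)
  t_ <- sweep(s %*% t(R), 2, tvec, "+")
  fit <- best_rigid(s, t_)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tvec, tolerance = 1e-9)
  resid <- apply_transform(fit, s) - t_
  expect_lt(sqrt(mean(resid^2)), 1e-9)
})

test_that("best_rigid stays proper on a reflected configuration", {
  # target is a reflected copy: the optimum over proper rotations differs
  # from the (disallowed) reflection; compare against an independent
  # numerical search over rotation angles
  s <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  t_ <- s
  t_[, 1] <- -t_[, 1]
  fit <- best_rigid(s, t_)
  expect_gt(det(fit$rotation), 0.99)
  rss <- function(ang) {
    R <- rotation_about(c(1, 0, 0), ang[1]) %*%
      rotation_about(c(0, 1, 0), ang[2]) %*%
      rotation_about(c(0, 0, 1), ang[3])
    # optimal translation for a given rotation aligns centroids
    tv <- colMeans(t_) - as.vector(R %*% colMeans(s))
    sum((sweep(s %*% t(R), 2, tv, "+") - t_)^2)
  }
  grid <- as.matrix(expand.grid(seq(0, 330, 30), seq(0, 330, 30),
                                seq(0, 330, 30)))
  vals <- apply(grid, 1, rss)
  best <- stats::optim(grid[which.min(vals), ], rss,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  fit_rss <- sum((apply_transform(fit, s) - t_)^2)
  expect_equal(fit_rss, best$value, tolerance = 1e-5)
})

test_that("best_rigid rejects degenerate input", {
  line <- cbind(1:5, 0, 0)
  expect_error(best_rigid(line, line), "degenerate|collinear")
  expect_error(best_rigid(matrix(1, 2, 3), matrix(1, 2, 3)), "3 point")
})

test_that("best_rigid is invariant under a common rigid motion", {
  set.seed(4)
  s <- matrix(rnorm(45), ncol = 3)
  t_ <- sweep(s %*% t(rotation_about(c(1, 1, 0), 25)), 2, c(3, 0, -1), "+")
  fit <- best_rigid(s, t_)
  g <- rigid_transform(rotation_about(c(2, -1, 1), 70), c(-4, 2, 9))
  fit2 <- best_rigid(apply_transform(g, s), apply_transform(g, t_))
  # conjugation identity: fit2 = g fit g^-1
  expect_equal(fit2$rotation,
               g$rotation %*% fit$rotation %*% t(g$rotation),
               tolerance = 1e-9)
})
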