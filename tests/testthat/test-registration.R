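test_that("fit_rigid recovers identity, pure translation and random poses", {
  set.seed(201)
  src <- matrix(rnorm(24, sd = 30), 8, 3)
  rownames(src) <- paste0("m", 1:8)

  f0 <- fit_rigid(src, src)
  expect_transform_equal(f0$transform, rigid_transform(), tol = 1e-12)
  expect_equal(f0$mean_error, 0, tolerance = 1e-12)

  ft <- fit_rigid(src, sweep(src, 2, c(1, 2, 3), "+"))
  expect_equal(ft$transform$translation, c(1, 2, 3), tolerance = 1e-12)
  expect_lt(max(abs(ft$transform$rotation - diag(3))), 1e-12)

  for (i in 1:10) {
    tf <- random_rigid_transform(170, 100)
    f <- fit_rigid(src, transform_points(tf, src))
    expect_transform_equal(f$transform, tf, tol = 1e-9)
    expect_lt(f$mean_error, 1e-9)
  }
})

test_that("fit_rigid matches points by label, not order", {
  set.seed(202)
  src <- matrix(rnorm(18, sd = 20), 6, 3)
  rownames(src) <- paste0("m", 1:6)
  tf <- random_rigid_transform(40, 30)
  dst <- transform_points(tf, src)[sample(6), ]
  f <- fit_rigid(src, dst)
  expect_transform_equal(f$transform, tf, tol = 1e-9)
})

test_that("fit_rigid rejects degenerate input", {
  expect_error(fit_rigid(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid(line, line + 0.1), "collinear")
})

test_that("fit_rigid agrees with a brute-force rotation-search oracle", {
  set.seed(203)
  for (n in c(4, 5, 6)) {
    src <- matrix(rnorm(3 * n, sd = 25), n, 3)
    # non-exact correspondence: add deformation so the optimum is non-trivial
    dst <- transform_points(random_rigid_transform(60, 40), src) +
      matrix(rnorm(3 * n, sd = 0.5), n, 3)
    f <- fit_rigid(src, dst)
    o <- brute_force_rigid(src, dst)
    expect_lt(max(abs(f$transform$rotation - o$rotation)), 1e-5)
    expect_lt(max(abs(f$transform$translation - o$translation)), 1e-5)
    expect_lte(sum(f$residuals^2), o$rss + 1e-8)
  }
})

test_that("mean error reflects a known single-marker displacement", {
  set.seed(204)
  src <- matrix(rnorm(27, sd = 30), 9, 3)
  dst <- src
  dst[1, ] <- dst[1, ] + c(0.9, 0, 0)
  f <- fit_rigid(src, dst)
  o <- brute_force_rigid(src, dst)
  expect_equal(f$mean_error, sqrt(o$rss / 9), tolerance = 1e-6)
  # displaced marker dominates the residuals
  expect_gt(f$residuals[1], max(f$residuals[-1]))
})

test_that("mean-error quality gate trips at 0.35 mm", {
  expect_true(fit_rigid(diag(3) * 10, diag(3) * 10)$flags[["me_ok"]])
  set.seed(205)
  src <- matrix(rnorm(30, sd = 30), 10, 3)
  dst <- src + matrix(rnorm(30, sd = 0.5), 10, 3)
  f <- fit_rigid(src, dst)
  expect_identical(unname(f$flags["me_ok"]), f$mean_error < 0.35)
})

test_that("condition number: cube corners give 1, collinear sets flag out", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * 10
  expect_equal(condition_number(cube), 1, tolerance = 1e-12)
  expect_identical(condition_number(cbind(1:5, 1:5, 1:5)), Inf)
  set.seed(206)
  src <- matrix(rnorm(30, sd = 30), 10, 3)
  expect_error(fit_rigid(cbind(1:4, 0, 0), cbind(1:4, 0, 0)), "collinear")
})

test_that("condition number matches an independent eigen-decomposition", {
  set.seed(207)
  for (i in 1:10) {
    pts <- matrix(rnorm(30, sd = c(40, 20, 5)), 10, 3, byrow = TRUE)
    ev <- eigen(crossprod(sweep(pts, 2, colMeans(pts))), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(condition_number(pts), sqrt(ev[1] / ev[3]),
                 tolerance = 1e-9)
  }
})

test_that("condition number is invariant under rigid motion and scale", {
  set.seed(208)
  pts <- matrix(rnorm(30, sd = 30), 10, 3)
  cn <- condition_number(pts)
  tf <- random_rigid_transform(120, 200)
  expect_equal(condition_number(transform_points(tf, pts)), cn,
               tolerance = 1e-9)
  expect_equal(condition_number(pts * 7.3), cn, tolerance = 1e-9)
})

test_that("increasing collinearity drives the condition number past 120", {
  set.seed(209)
  base <- matrix(rnorm(30, sd = 30), 10, 3)
  squash <- function(f) { p <- base; p[, 2:3] <- p[, 2:3] * f; p }
  cns <- sapply(c(1, 0.3, 0.1, 0.02, 0.005), function(f)
    condition_number(squash(f)))
  expect_true(all(diff(cns) > 0))
  expect_gt(cns[5], 120)
})

test_that("ICP recovers exact and perturbed-init poses", {
  set.seed(210)
  for (kind in c("stem", "cup")) {
    mdl <- make_implant_model(kind)
    tf <- random_rigid_transform(20, 40)
    cloud <- transform_points(tf, mdl$surface_points)
    f_exact <- fit_model_pose(mdl, cloud, init = tf)
    expect_transform_equal(f_exact$transform, tf, tol = 1e-9)
    expect_lt(f_exact$mean_error, 1e-9)
    for (i in 1:5) {
      init <- compose_transforms(random_rigid_transform(3, 4), tf)
      f <- fit_model_pose(mdl, cloud, init = init)
      expect_true(f$converged)
      expect_transform_equal(f$transform, tf, tol = 1e-6)
    }
  }
})

test_that("ICP residual tracks point noise and the pose error shrinks with n", {
  set.seed(211)
  mdl <- make_implant_model("stem", n_points = 400)
  tf <- random_rigid_transform(10, 20)
  sigma <- 0.2
  pose_err <- sapply(c(60, 300), function(n) {
    idx <- sample(nrow(mdl$surface_points), n)
    cloud <- transform_points(tf, mdl$surface_points[idx, ]) +
      matrix(rnorm(3 * n, sd = sigma), n, 3)
    f <- fit_model_pose(mdl, cloud, init = tf)
    expect_gt(f$mean_error, 0.4 * sigma)
    expect_lt(f$mean_error, 2.5 * sigma)
    max(abs(f$transform$rotation - tf$rotation))
  })
  expect_lt(pose_err[2], pose_err[1])
})

test_that("ICP coarse-aligns an uninitialised stem cloud", {
  set.seed(212)
  stem <- make_implant_model("stem")
  tf <- random_rigid_transform(60, 40)
  idx <- sample(nrow(stem$surface_points), 170)
  cl <- transform_points(tf, stem$surface_points[idx, ])
  f <- fit_model_pose(stem, cl)
  expect_true(f$converged)
  expect_transform_equal(f$transform, tf, tol = 1e-8)
})

test_that("ICP refuses empty or non-finite clouds", {
  mdl <- make_implant_model("cup")
  expect_error(fit_model_pose(mdl, matrix(numeric(0), 0, 3)), "empty")
  expect_error(fit_model_pose(mdl, matrix(c(1, NA, 3), 1, 3)), "finite")
})
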