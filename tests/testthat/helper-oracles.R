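# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the rigid-fit oracle searches rotation space numerically
# instead of using the SVD solution, the interval oracle evaluates binomial
# tail sums instead of beta quantiles.

# Brute-force rigid superposition: Nelder-Mead over Cardan angles from a
# grid of starting rotations; translation is centroid-matched given the
# rotation. Good to ~1e-7 on small point sets.
brute_force_rigid <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  obj <- function(ang) {
    R <- rotation_from_cardan(ang[1], ang[2], ang[3])
    sum((A %*% t(R) - B)^2)
  }
  starts <- expand.grid(rx = c(-120, 0, 120), ry = c(-60, 0, 60),
                        rz = c(-120, 0, 120))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-16))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  R <- rotation_from_cardan(best$par[1], best$par[2], best$par[3])
  list(rotation = R, translation = cd - as.numeric(R %*% cs),
       rss = best$value)
}

# Clopper-Pearson defining tail equations evaluated by direct summation
binom_tail_upper <- function(k, n, p) sum(stats::dbinom(k:n, n, p))   # P(X>=k)
binom_tail_lower <- function(k, n, p) sum(stats::dbinom(0:k, n, p))   # P(X<=k)

# random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# sagittal mirror (x -> -x) of a whole examination; sides toggle
mirror_examination <- function(exam) {
  M <- diag(c(-1, 1, 1))
  mir_tf <- function(tf) rigid_transform(M %*% tf$rotation %*% M,
                                         as.numeric(M %*% tf$translation))
  mir_pts <- function(p) { p[, 1] <- -p[, 1]; p }
  # model-to-scanner poses pick up a model-frame z-flip (both implant
  # models are symmetric about their z = 0 plane)
  Fz <- diag(c(1, 1, -1))
  mir_pose <- function(tf) rigid_transform(M %*% tf$rotation %*% Fz,
                                           as.numeric(M %*% tf$translation))
  exam$pelvis_markers <- mir_pts(exam$pelvis_markers)
  exam$femur_markers <- mir_pts(exam$femur_markers)
  for (m in names(exam$implant_clouds)) {
    exam$implant_clouds[[m]] <- lapply(exam$implant_clouds[[m]], mir_pts)
    exam$init_pose[[m]] <- lapply(exam$init_pose[[m]], mir_pose)
  }
  exam$patient_pose <- mir_tf(exam$patient_pose)
  exam$side <- if (exam$side == "left") "right" else "left"
  exam
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
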