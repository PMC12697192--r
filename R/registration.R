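#' Least-squares rigid fit of corresponding point sets
#'
#' Orthogonal superposition (Kabsch): finds the proper rotation and
#' translation minimising the sum of squared distances between matched
#' points. Points are matched by row label when both sets are labelled,
#' otherwise by row order. Reflection solutions are rejected by flipping the
#' sign of the smallest singular vector when the determinant is negative.
#'
#' The returned fit carries the two RSA quality metrics: the mean error of
#' rigid body fitting (RMS residual after superposition, threshold 0.35 mm)
#' and the condition number of the source marker configuration
#' (threshold 120).
#'
#' @param src,dst point sets (n x 3, optionally with matching rownames),
#'   n >= 3 and not collinear.
#' @return A `fit_result` list: `transform`, `residuals` (per-point mm),
#'   `mean_error` (mm), `condition_number`, and logical `flags`
#'   (`cn_ok`, `me_ok`).
#' @export
fit_rigid <- function(src, dst) {
  src <- as_pointset(src); dst <- as_pointset(dst)
  if (!is.null(rownames(src)) && !is.null(rownames(dst))) {
    common <- intersect(rownames(src), rownames(dst))
    if (length(common) < 3L) stop("fewer than 3 matched labelled points")
    src <- src[common, , drop = FALSE]
    dst <- dst[common, , drop = FALSE]
  }
  n <- nrow(src)
  if (n < 3L || nrow(dst) != n) stop("need >= 3 matched points")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  cn <- condition_number(src)
  # the rigid fit is well-posed whenever the markers are non-collinear
  # (second singular value > 0); planar or 3-marker sets fit fine but get
  # an infinite condition number and a failed CN gate
  sv_src <- svd(A, nu = 0, nv = 0)$d
  if (sv_src[2] < 1e-9 * max(sv_src[1], 1))
    stop("degenerate (collinear) marker configuration")
  sv <- svd(crossprod(A, B))          # H = A^T B;  R = V S U^T
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  tr <- cd - as.numeric(R %*% cs)
  tf <- rigid_transform(R, tr)
  res <- sqrt(rowSums((transform_points(tf, src) - dst)^2))
  me <- mean_error(res)
  structure(list(transform = tf, residuals = res, mean_error = me,
                 condition_number = cn, n_points = n,
                 flags = c(cn_ok = cn < 120, me_ok = me < 0.35)),
            class = "fit_result")
}

#' Mean error of rigid body fitting
#'
#' Root-mean-square residual after optimal superposition of the same marker
#' set across two examinations; values above 0.35 mm indicate unstable
#' markers.
#'
#' @param residuals per-point residual distances (mm).
#' @return RMS residual (mm).
#' @export
mean_error <- function(residuals) {
  if (length(residuals) == 0L) stop("empty residuals")
  sqrt(mean(residuals^2))
}

#' Condition number of a marker configuration
#'
#' Ratio of largest to smallest singular value of the centroid-centred
#' coordinate matrix. High values indicate near-collinear marker spread and
#' unstable rigid fits; the conventional acceptance threshold is 120.
#' Numerically singular configurations return `Inf`.
#'
#' @param points n x 3 point set, n >= 3.
#' @export
condition_number <- function(points) {
  points <- as_pointset(points)
  if (nrow(points) < 3L) stop("need >= 3 points")
  s <- svd(sweep(points, 2, colMeans(points)), nu = 0, nv = 0)$d
  if (s[3] < 1e-12 * max(s[1], 1)) return(Inf)
  s[1] / s[3]
}

#' Fit an implant model pose to an observed point cloud (ICP)
#'
#' Iterative closest point: alternates nearest-neighbour correspondence from
#' cloud points to model surface points with a rigid Kabsch fit, until the
#' pose update falls below `tol` (mm, measured as the maximum displacement of
#' a cloud point) or `max_iter` is reached. With no initial pose a coarse
#' alignment from centroids and principal axes is used, trying the four
#' proper-rotation sign combinations and keeping the best.
#'
#' The coarse initialiser relies on distinct principal axes; for nearly
#' rotationally symmetric models (the cup) the azimuth about the symmetry
#' axis is undetermined and an explicit `init` should be supplied, e.g.
#' the pose recorded by the upstream localisation stage.
#'
#' @param model `implant_model` (see [make_implant_model()]).
#' @param cloud observed surface samples, n x 3 (mm).
#' @param init optional `rigid_transform` initial model-to-cloud pose.
#' @param tol convergence tolerance (mm); `max_iter` iteration cap.
#' @param max_iter maximum ICP iterations.
#' @param restarts number of deterministic perturbed restarts around the
#'   first converged pose (small tilts about the model axes); the pose with
#'   the lowest RMS nearest-neighbour distance wins. Guards against
#'   lattice-alignment local minima on nearly symmetric implants.
#' @return `fit_result` with `transform` (model -> cloud pose), residuals,
#'   `mean_error` (RMS nearest-neighbour distance, mm), `converged`,
#'   `iterations`.
#' @export
fit_model_pose <- function(model, cloud, init = NULL, tol = 1e-6,
                           max_iter = 200L, restarts = 18L) {
  cloud <- as_pointset(cloud)
  if (nrow(cloud) == 0L) stop("empty cloud")
  rownames(cloud) <- NULL                 # ICP matches by geometry, not label
  surf <- model$surface_points
  rownames(surf) <- NULL
  if (is.null(init)) init <- coarse_align(surf, cloud)
  best <- icp_run(surf, cloud, init, tol, max_iter)
  if (restarts > 0L && best$mean_error > 1e-9) {
    ctr <- colMeans(surf)
    # rotation (deg, about the model centroid) + model-frame slide (mm):
    # tilts escape ring-alignment minima, slides escape along-axis ones
    perts <- list(list(r = c(5, 0, 0)), list(r = c(-5, 0, 0)),
                  list(r = c(0, 0, 5)), list(r = c(0, 0, -5)),
                  list(t = c(0, 6, 0)), list(t = c(0, -6, 0)),
                  list(r = c(10, 0, 0)), list(r = c(-10, 0, 0)),
                  list(r = c(0, 0, 10)), list(r = c(0, 0, -10)),
                  list(r = c(0, 5, 0)), list(r = c(0, -5, 0)),
                  list(r = c(0, 0, -1.5), t = c(0, 6, 0)),
                  list(r = c(0, 0, 1.5), t = c(0, -6, 0)),
                  list(r = c(0, 12, 0)), list(r = c(0, -12, 0)),
                  list(r = c(0, 16, 0)), list(r = c(0, -16, 0)))
    for (k in seq_len(min(restarts, length(perts)))) {
      p <- perts[[k]]
      r <- if (is.null(p$r)) c(0, 0, 0) else p$r
      tl <- if (is.null(p$t)) c(0, 0, 0) else p$t
      Rp <- rotation_from_cardan(r[1], r[2], r[3])
      pert <- rigid_transform(Rp, ctr - as.numeric(Rp %*% ctr) + tl)
      cand <- icp_run(surf, cloud,
                      compose_transforms(best$transform, pert),
                      tol, max_iter)
      if (cand$mean_error < best$mean_error) best <- cand
      if (best$mean_error < 1e-9) break
    }
  }
  structure(c(best, list(condition_number = NA_real_,
                         flags = c(converged = best$converged))),
            class = "fit_result")
}

icp_run <- function(surf, cloud, init, tol, max_iter) {
  tf <- init
  pos <- transform_points(tf, surf)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    nn <- nearest_neighbours(cloud, pos)
    fit <- fit_rigid(surf[nn, , drop = FALSE], cloud)
    newpos <- transform_points(fit$transform, surf)
    step <- sqrt(max(rowSums((newpos - pos)^2)))
    pos <- newpos
    tf <- fit$transform
    if (step < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  nn <- nearest_neighbours(cloud, pos)
  res <- sqrt(rowSums((cloud - pos[nn, , drop = FALSE])^2))
  list(transform = tf, residuals = res, mean_error = sqrt(mean(res^2)),
       converged = converged, iterations = it)
}

# index of nearest row of `ref` for each row of `query` (brute force; the
# clouds this pipeline handles are a few hundred points)
nearest_neighbours <- function(query, ref) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) -
    2 * query %*% t(ref) +
    outer(rep(1, nrow(query)), rowSums(ref^2))
  max.col(-d2, ties.method = "first")
}

# PCA-based coarse alignment with 4-way sign disambiguation
coarse_align <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(dst), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  best <- NULL; best_err <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))     # keeps det = +1
    R <- ed %*% S %*% t(es)
    tf <- rigid_transform(R, cd - as.numeric(R %*% cs))
    pos <- transform_points(tf, src)
    nn <- nearest_neighbours(dst, pos)
    err <- mean(rowSums((dst - pos[nn, , drop = FALSE])^2))
    if (err < best_err) { best_err <- err; best <- tf }
  }
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: mean_error =", signif(x$mean_error, 4), "mm")
  if (is.finite(x$condition_number))
    cat(", condition_number =", signif(x$condition_number, 4))
  if (!is.null(x$converged))
    cat(", converged =", x$converged, "in", x$iterations, "iterations")
  cat("\n  flags:", paste(names(x$flags), x$flags, collapse = ", "), "\n")
  invisible(x)
}
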