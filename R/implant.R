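#' Parametric implant models
#'
#' Stand-ins for manufacturer CAD geometry: a tapered femoral stem with a
#' neck, and an acetabular cup modelled as a hemispherical shell with rim
#' screw-hole features. The screw holes break the hemisphere's rotational
#' symmetry about its pole so the cup pose is identifiable from surface
#' geometry alone.
#'
#' Models are built in a canonical implant frame: stem long axis along +y
#' (tip at the origin, shoulder above), neck pointing into the +x half-plane;
#' cup centred at the origin with its pole along +y.
#'
#' @param kind `"stem"` or `"cup"`.
#' @param size_label character size category (e.g. `"12"`, `"52"`); for
#'   stems, an offset variant can be appended (`"12/varus"`).
#' @param stem_length_mm,neck_length_mm,neck_angle_deg stem geometry; the
#'   neck angle is measured from the long axis in the x-y plane.
#' @param cup_radius_mm cup hemisphere radius.
#' @param n_points approximate number of surface sample points.
#' @return An `implant_model`: `kind`, `size_label`, `surface_points`
#'   (labelled n x 3 matrix, mm) and `landmarks` (named 3-vectors — stem:
#'   `tip`, `shoulder`, `neck_base`, `head_center`; cup: `center`, `pole`).
#' @export
make_implant_model <- function(kind = c("stem", "cup"), size_label = "1",
                               stem_length_mm = 120, neck_length_mm = 35,
                               neck_angle_deg = 48, cup_radius_mm = 26,
                               n_points = 240) {
  kind <- match.arg(kind)
  if (kind == "stem") {
    if (stem_length_mm <= 0) stop("degenerate geometry: zero-length stem axis")
    if (neck_angle_deg <= 0 || neck_angle_deg >= 90)
      stop("neck axis parallel (or orthogonal-degenerate) to stem long axis")
    # shaft: elliptical cross-section rings with a distal taper; ring
    # heights follow a power law and the azimuth count tracks the ring
    # size, so the sampling has no translational lattice along the shaft
    # (a regular lattice gives ICP slide-by-one-ring local minima)
    n_lev <- max(3L, round(0.75 * n_points / 9))
    y <- stem_length_mm * ((seq_len(n_lev) - 0.5) / n_lev)^1.3
    frac <- y / stem_length_mm
    a <- 4 + 8 * frac          # half-widths: distal taper, elliptical section
    b <- 2.5 + 4 * frac
    shaft <- do.call(rbind, lapply(seq_len(n_lev), function(i) {
      n_az <- max(6L, round(5 + 0.6 * a[i]))
      th <- seq(0, 2 * pi, length.out = n_az + 1L)[-(n_az + 1L)]
      cbind(a[i] * cos(th), y[i], b[i] * sin(th))
    }))
    ang <- neck_angle_deg * pi / 180
    ndir <- c(sin(ang), cos(ang), 0)   # unit neck direction in x-y plane
    neck_base <- c(0, stem_length_mm * 0.92, 0)
    n_ns <- max(2L, round(0.25 * n_points / 6))
    s <- 0.15 + 0.85 * ((seq_len(n_ns) - 0.5) / n_ns)^1.4
    neck <- do.call(rbind, lapply(s, function(f) {
      ctr <- neck_base + f * neck_length_mm * ndir
      u <- c(cos(ang), -sin(ang), 0)   # circle basis orthogonal to ndir
      v <- c(0, 0, 1)
      t6 <- seq(0, 2 * pi, length.out = 7L)[-7L]
      t(ctr + 6 * (outer(u, cos(t6)) + outer(v, sin(t6))))
    }))
    surface <- rbind(shaft, neck)
    rownames(surface) <- sprintf("s%03d", seq_len(nrow(surface)))
    landmarks <- list(tip = c(0, 0, 0),
                      shoulder = c(0, stem_length_mm, 0),
                      neck_base = neck_base,
                      head_center = neck_base + neck_length_mm * ndir)
  } else {
    if (cup_radius_mm <= 0) stop("degenerate geometry: non-positive cup radius")
    # hemisphere about the origin, pole +y: latitude rings with azimuth sets
    # closed under negation, so the point set is exactly symmetric about
    # the z = 0 plane (left implants are sagittal mirror images)
    n_ring <- 12L
    # area-uniform polar positions give irregular ring spacing, and the
    # azimuth count grows with the ring circumference: both break the
    # lattice coherence that would otherwise give ICP tilt local minima
    beta <- acos(1 - (seq_len(n_ring) - 0.35) / n_ring)
    hemi <- do.call(rbind, lapply(seq_len(n_ring), function(k) {
      b <- beta[k]
      n_az <- max(6L, round(n_points / n_ring * sin(b) * 1.5))
      az <- seq(0, 2 * pi, length.out = n_az + 1L)[-(n_az + 1L)]
      cup_radius_mm * cbind(sin(b) * cos(az), cos(b), sin(b) * sin(az))
    }))
    # rim screw-hole markers, slightly proud of the shell, at azimuths
    # {0, 70, -70} deg: asymmetric under pole rotation, symmetric under the
    # z-flip (the 70 and -70 holes exchange)
    holes <- do.call(rbind, lapply(c(0, 70, -70), function(azd) {
      a <- azd * pi / 180
      r <- 1.04 * cup_radius_mm
      t(vapply(c(-2, 0, 2), function(dz)
        c(r * cos(a + dz * 0.03), 0.08 * cup_radius_mm, r * sin(a + dz * 0.03)),
        numeric(3)))
    }))
    surface <- rbind(hemi, holes)
    rownames(surface) <- sprintf("c%03d", seq_len(nrow(surface)))
    landmarks <- list(center = c(0, 0, 0), pole = c(0, cup_radius_mm, 0))
  }
  structure(list(kind = kind, size_label = size_label,
                 surface_points = as_pointset(surface),
                 landmarks = lapply(landmarks, as.numeric),
                 radius_mm = if (kind == "cup") cup_radius_mm else NA_real_),
            class = "implant_model")
}

#' @export
print.implant_model <- function(x, ...) {
  cat("implant_model:", x$kind, "size", x$size_label, "-",
      nrow(x$surface_points), "surface points,",
      length(x$landmarks), "landmarks\n")
  invisible(x)
}

#' Anatomic coordinate frames
#'
#' A frame is an origin plus three orthonormal right-handed axes labelled
#' x (medial+), y (superior+), z (anterior+). Migration components are the
#' relative implant motion decomposed on these axes.
#'
#' `build_stem_frame()` constructs the implant-based stem frame: y parallel
#' to the stem long axis (shoulder - tip), x the component of the neck axis
#' orthogonal to y (the neck points medially), z = x cross y.
#' `build_table_frame()` is the scanner/calibration-cage frame — the identity
#' frame of lab space — used for the cup.
#'
#' The x-axis is signed so that z = x cross y points anteriorly
#' (`anterior_hint`): for a right hip x then points medially along the neck;
#' for a left hip (mirrored anatomy) it points laterally, which is what
#' makes a single side-mirroring rule (negate Tx, Ry, Rz; see
#' [mirror_to_right()]) valid for both sides. Pass `anterior_hint = NULL`
#' to keep the raw neck-signed x.
#'
#' @param landmarks named list with `tip`, `shoulder` and either `neck_base`
#'   plus `head_center` or a `neck_dir` vector.
#' @param origin frame origin (mm).
#' @param anterior_hint approximate lab-frame anterior direction used to
#'   disambiguate the sign of the x-axis.
#' @return An `anatomic_frame`: `origin` (3-vector) and `axes` (3x3 matrix
#'   whose columns are the x, y, z unit vectors).
#' @export
build_stem_frame <- function(landmarks, origin = landmarks$tip,
                             anterior_hint = c(0, 0, 1)) {
  yax <- landmarks$shoulder - landmarks$tip
  ny <- sqrt(sum(yax^2))
  if (ny < 1e-9) stop("zero-length stem axis")
  yax <- yax / ny
  ndir <- if (!is.null(landmarks$neck_dir)) landmarks$neck_dir
          else landmarks$head_center - landmarks$neck_base
  xax <- ndir - sum(ndir * yax) * yax
  nx <- sqrt(sum(xax^2))
  if (nx < 1e-9) stop("neck axis parallel to stem long axis")
  xax <- xax / nx
  zax <- c(xax[2] * yax[3] - xax[3] * yax[2],
           xax[3] * yax[1] - xax[1] * yax[3],
           xax[1] * yax[2] - xax[2] * yax[1])
  if (!is.null(anterior_hint) && sum(zax * anterior_hint) < 0) {
    xax <- -xax
    zax <- -zax
  }
  structure(list(origin = as.numeric(origin),
                 axes = cbind(x = xax, y = yax, z = zax)),
            class = "anatomic_frame")
}

#' @rdname build_stem_frame
#' @export
build_table_frame <- function(origin = c(0, 0, 0)) {
  ax <- diag(3)
  colnames(ax) <- c("x", "y", "z")
  structure(list(origin = as.numeric(origin), axes = ax),
            class = "anatomic_frame")
}

#' @export
print.anatomic_frame <- function(x, ...) {
  cat("anatomic_frame at", format(round(x$origin, 3)), "\n")
  print(round(x$axes, 6))
  invisible(x)
}
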