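#' Euclidean total of three components
#'
#' `sqrt(x^2 + y^2 + z^2)`; total translation and total rotation are the
#' Euclidean norms of their three components.
#'
#' @param x,y,z finite numeric components.
#' @export
euclidean_total <- function(x, y, z) {
  if (any(!is.finite(c(x, y, z)))) stop("non-finite input")
  sqrt(x^2 + y^2 + z^2)
}

#' Report a migration result as if the hip were right-sided
#'
#' Left-hip results are sagittally mirrored into right-hip convention:
#' x-translation, y-rotation and z-rotation change sign; y- and
#' z-translations, x-rotation and both Euclidean totals are unchanged
#' (conjugation of the motion by the reflection through the sagittal
#' plane). Right-hip results pass through unchanged. The output is always
#' flagged as right-convention.
#'
#' @param dof named numeric with `Tx, Ty, Tz, Rx, Ry, Rz` (and optionally
#'   `Ttot`, `Rtot`), or a `migration_dof` row.
#' @param side `"left"` or `"right"`.
#' @export
mirror_to_right <- function(dof, side) {
  if (!side %in% c("left", "right")) stop("unknown side: ", side)
  if (side == "left")
    for (k in c("Tx", "Ry", "Rz")) dof[[k]] <- -dof[[k]]
  dof
}

#' Measure 6-DOF migration between two examinations
#'
#' Implements the measurement chain: (1) rigid superposition of the
#' reference-bone markers aligns the follow-up scan to the baseline scan
#' (quality-gated by condition number < 120 and mean error < 0.35 mm);
#' (2) the implant model is pose-fitted (ICP) to the implant cloud in both
#' scans; (3) the relative implant transform, expressed in the baseline
#' patient/table frame, is decomposed on the segment's anatomic frame —
#' implant-based for the stem (y along the stem long axis), the table frame
#' for the cup — into Cardan angles (x-y-z order) plus the translation of
#' the implant reference point (model centroid); (4) left hips are mirrored
#' to right-hip convention. Quality failures flag the record; nothing is
#' silently dropped.
#'
#' @param baseline,followup examinations from [generate_study()].
#' @param model `implant_model` for the target implant.
#' @param target `"stem"` or `"cup"`; the reference bone defaults to femur
#'   for the stem and pelvis for the cup.
#' @param method which implant observation to use (`"ctrsa"`, `"mbrsa"`).
#' @param reference override of the reference bone (`"femur"`, `"pelvis"`).
#' @return A one-row `migration_dof` data frame: Tx, Ty, Tz (mm), Rx, Ry,
#'   Rz (deg), Ttot, Rtot, side (always reported right), segment, method,
#'   condition number `cn`, mean error `me`, and gate flags.
#' @export
analyze_pair <- function(baseline, followup, model,
                         target = c("stem", "cup"),
                         method = "ctrsa", reference = NULL) {
  target <- match.arg(target)
  if (baseline$subject != followup$subject) stop("subject mismatch")
  if (is.null(reference))
    reference <- if (target == "stem") "femur" else "pelvis"
  mk <- paste0(ifelse(reference == "femur", "femur", "pelvis"), "_markers")
  if (is.null(baseline[[mk]]) || is.null(followup[[mk]]))
    stop("missing reference markers")
  # work in the baseline patient/table frame (undo the recorded scan pose)
  to_scene <- invert_transform(baseline$patient_pose)
  mk0 <- transform_points(to_scene, baseline[[mk]])
  ref_fit <- fit_rigid(followup[[mk]], mk0)
  cl0 <- transform_points(to_scene, baseline$implant_clouds[[method]][[target]])
  in0 <- compose_transforms(to_scene, baseline$init_pose[[method]][[target]])
  p0 <- fit_model_pose(model, cl0, init = in0)
  cl1 <- transform_points(ref_fit$transform,
                          followup$implant_clouds[[method]][[target]])
  in1 <- compose_transforms(ref_fit$transform,
                            followup$init_pose[[method]][[target]])
  p1 <- fit_model_pose(model, cl1, init = in1)
  if (!p0$converged || !p1$converged)
    warning("model pose fit did not converge for ", baseline$subject)
  D <- compose_transforms(p1$transform, invert_transform(p0$transform))
  ref_pt <- as.numeric(transform_points(
    p0$transform, rbind(colMeans(model$surface_points))))
  frame <- if (target == "stem") {
    lm <- lapply(model$landmarks, function(p)
      as.numeric(transform_points(p0$transform, rbind(p))))
    build_stem_frame(lm)
  } else build_table_frame()
  dof <- as.list(transform_to_dof(D, frame, ref_pt))
  dof <- mirror_to_right(dof, baseline$side)
  out <- data.frame(subject = baseline$subject, side = "right",
                    native_side = baseline$side, method = method,
                    segment = target, timepoint = followup$timepoint,
                    replicate = followup$replicate,
                    Tx = dof$Tx, Ty = dof$Ty, Tz = dof$Tz,
                    Rx = dof$Rx, Ry = dof$Ry, Rz = dof$Rz,
                    Ttot = euclidean_total(dof$Tx, dof$Ty, dof$Tz),
                    Rtot = euclidean_total(dof$Rx, dof$Ry, dof$Rz),
                    cn = ref_fit$condition_number, me = ref_fit$mean_error,
                    cn_ok = unname(ref_fit$flags["cn_ok"]),
                    me_ok = unname(ref_fit$flags["me_ok"]))
  class(out) <- c("migration_dof", class(out))
  out
}

#' Analyze a whole simulated study into a tidy long table
#'
#' Runs [analyze_pair()] for every follow-up examination (including
#' double-examination replicates) against the subject's baseline scan, for
#' the requested methods and segments, and pivots the six DOF plus totals
#' into long format.
#'
#' @param study output of [generate_study()].
#' @param methods,segments subsets to analyze.
#' @return Long data frame: subject, side, method, segment, dof, timepoint,
#'   replicate, value, cn, me, cn_ok, me_ok.
#' @export
analyze_study <- function(study, methods = names(study$config$noise_sd),
                          segments = c("stem", "cup")) {
  exams <- study$exams
  key <- vapply(exams, function(e) e$subject, "")
  rows <- list()
  for (sid in unique(key)) {
    sub <- exams[key == sid]
    tps <- vapply(sub, function(e) e$timepoint, 0)
    reps <- vapply(sub, function(e) e$replicate, 0L)
    base <- sub[[which(tps == 0 & reps == 1L)[1]]]
    for (e in sub) {
      if (e$timepoint == 0 && e$replicate == 1L) next
      for (m in methods) for (seg in segments) {
        wide <- analyze_pair(base, e, study$models[[seg]], target = seg,
                             method = m)
        rows[[length(rows) + 1L]] <- wide
      }
    }
  }
  wide <- do.call(rbind, rows)
  long <- do.call(rbind, lapply(c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz",
                                  "Ttot", "Rtot"), function(d)
    data.frame(subject = wide$subject, side = wide$side,
               native_side = wide$native_side, method = wide$method,
               segment = wide$segment, dof = d,
               timepoint = wide$timepoint, replicate = wide$replicate,
               value = wide[[d]], cn = wide$cn, me = wide$me,
               cn_ok = wide$cn_ok, me_ok = wide$me_ok)))
  long[order(long$subject, long$method, long$segment, long$dof,
             long$timepoint, long$replicate), ]
}
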