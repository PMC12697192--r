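#' Configuration of a simulated migration follow-up study
#'
#' Bundles every knob of the virtual study: cohort size and laterality,
#' visit schedule, bone-marker geometry, the piecewise-linear ground-truth
#' migration model, per-method measurement noise, double examinations and
#' planned-vs-used implant size probabilities.
#'
#' Defaults reproduce the structure of a 26-patient uncemented THA cohort
#' followed at 0, 3, 12 and 24 months with 9 tantalum markers per bone
#' segment, two measurement methods (CT-based RSA, less noisy, and
#' model-based RSA), a duplicated 3-month visit with intermediate
#' repositioning, and migration that is fast in the first 3 months and
#' nearly flat afterwards.
#'
#' DOF vectors are ordered `Tx, Ty, Tz` (mm) then `Rx, Ry, Rz` (degrees),
#' in right-hip convention: positive translations medial, superior,
#' anterior; positive rotations anterior tilt, internal rotation, valgus
#' (stem) / decreased inclination (cup).
#'
#' Measurement noise is specified on the DOF scale: each observation of an
#' implant perturbs its true pose by an independent small rigid transform
#' whose six components are drawn `N(0, sd^2)` on the respective axes, so a
#' configured SD is directly the SD of the measured migration component.
#' `point_jitter_sd` adds optional iid Gaussian noise to each observed
#' surface point coordinate on top.
#'
#' @param n_subjects number of patients.
#' @param prop_left proportion of left hips.
#' @param timepoints_months strictly increasing visit times, starting at 0.
#' @param markers_per_segment tantalum markers per bone segment.
#' @param marker_spread_mm scale of the marker cloud (ellipsoid semi-axis).
#' @param marker_instability_prob per-marker probability of an independent
#'   displacement at a follow-up visit; `marker_instability_sd` its SD (mm).
#' @param marker_instability_sd SD (mm) of an unstable marker's displacement.
#' @param slope_early,slope_late named lists with elements `stem` and `cup`,
#'   each a 6-vector of per-month migration rates for months 0-3 and 3-24.
#' @param subject_sd between-subject SD of the per-DOF early slope
#'   (units/month); late slopes get one tenth of it.
#' @param noise_sd_ctrsa,noise_sd_mbrsa 6-vectors of per-DOF measurement
#'   noise SDs (mm / degrees) for the two methods.
#' @param point_jitter_sd per-coordinate Gaussian noise on observed surface
#'   points (mm).
#' @param double_exam_timepoint visit (months) scanned twice with
#'   repositioning, or `NA` to disable.
#' @param reposition_rot_deg,reposition_trans_mm bounds of the random rigid
#'   patient repositioning between scans.
#' @param plan_match_prob_cup,plan_match_prob_stem,plan_exact_prob_stem
#'   probabilities that the planned cup size, stem size, and exact stem
#'   (size and offset variant) match the implant actually used.
#' @param seed integer RNG seed; identical config and seed give identical
#'   studies.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_subjects = 26,
                         prop_left = 14 / 26,
                         timepoints_months = c(0, 3, 12, 24),
                         markers_per_segment = 9,
                         marker_spread_mm = 40,
                         marker_instability_prob = 0,
                         marker_instability_sd = 0.5,
                         slope_early = list(
                           stem = c(0.01, -0.037, 0.01, 0.02, -0.18, 0.01),
                           cup = c(0.02, 0.103, 0.01, 0.02, 0.02, 0.167)),
                         slope_late = list(
                           stem = c(0, 0, 0, 0, -0.002, 0),
                           cup = c(0, 0.002, 0, 0, 0, 0.001)),
                         subject_sd = 0.02,
                         noise_sd_ctrsa = c(0.028, 0.05, 0.021,
                                            0.028, 0.12, 0.028),
                         noise_sd_mbrsa = c(0.092, 0.071, 0.099,
                                            0.156, 0.205, 0.078),
                         point_jitter_sd = 0,
                         double_exam_timepoint = 3,
                         reposition_rot_deg = 15,
                         reposition_trans_mm = 50,
                         plan_match_prob_cup = 25 / 26,
                         plan_match_prob_stem = 23 / 26,
                         plan_exact_prob_stem = 16 / 26,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), prop_left = prop_left,
              timepoints_months = as.numeric(timepoints_months),
              markers_per_segment = as.integer(markers_per_segment),
              marker_spread_mm = marker_spread_mm,
              marker_instability_prob = marker_instability_prob,
              marker_instability_sd = marker_instability_sd,
              slope_early = lapply(slope_early, as.numeric),
              slope_late = lapply(slope_late, as.numeric),
              subject_sd = subject_sd,
              noise_sd = list(ctrsa = rep_len(as.numeric(noise_sd_ctrsa), 6L),
                              mbrsa = rep_len(as.numeric(noise_sd_mbrsa), 6L)),
              point_jitter_sd = point_jitter_sd,
              double_exam_timepoint = double_exam_timepoint,
              reposition_rot_deg = reposition_rot_deg,
              reposition_trans_mm = reposition_trans_mm,
              plan_match_prob_cup = plan_match_prob_cup,
              plan_match_prob_stem = plan_match_prob_stem,
              plan_exact_prob_stem = plan_exact_prob_stem,
              seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  tp <- cfg$timepoints_months
  if (length(tp) < 1L || tp[1] != 0 || any(diff(tp) <= 0))
    stop("timepoints must be strictly increasing and start at 0")
  sds <- c(cfg$subject_sd, cfg$noise_sd$ctrsa, cfg$noise_sd$mbrsa,
           cfg$point_jitter_sd, cfg$marker_instability_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  pr <- c(cfg$prop_left, cfg$marker_instability_prob,
          cfg$plan_match_prob_cup, cfg$plan_match_prob_stem,
          cfg$plan_exact_prob_stem)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$plan_exact_prob_stem > cfg$plan_match_prob_stem)
    stop("exact stem match probability cannot exceed size match probability")
  if (cfg$n_subjects < 1L) stop("need at least one subject")
  for (seg in c("stem", "cup")) {
    if (length(cfg$slope_early[[seg]]) != 6L ||
        length(cfg$slope_late[[seg]]) != 6L)
      stop("slopes must be 6-vectors (Tx, Ty, Tz, Rx, Ry, Rz)")
  }
  invisible(cfg)
}

dof_names <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")

# rigid transform realizing a 6-DOF pose (frame coords, about ref point)
dof_to_transform <- function(dof6, frame, ref_point) {
  Q <- frame$axes
  Rw <- Q %*% rotation_from_cardan(dof6[4], dof6[5], dof6[6]) %*% t(Q)
  tw <- as.numeric(Q %*% dof6[1:3]) + ref_point - as.numeric(Rw %*% ref_point)
  rigid_transform(Rw, tw)
}

# inverse: decompose a world transform into 6 DOF on a frame about ref point
transform_to_dof <- function(tf, frame, ref_point) {
  Q <- frame$axes
  ang <- cardan_from_rotation(t(Q) %*% tf$rotation %*% Q)
  dp <- transform_points(tf, matrix(ref_point, 1)) - rbind(ref_point)
  stats::setNames(c(as.numeric(dp %*% Q), ang), dof_names)
}

# markers uniform in an ellipsoidal shell around `center`
sample_markers <- function(n, center, spread, prefix) {
  pts <- matrix(0, n, 3)
  semi <- spread * c(1, 0.8, 0.6)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3, -1, 1)
      r2 <- sum(u^2)
      if (r2 <= 1 && r2 >= 0.25) break
    }
    pts[i, ] <- center + semi * u
  }
  rownames(pts) <- paste0(prefix, seq_len(n))
  pts
}

mirror_x <- function(points) {
  points[, 1] <- -points[, 1]
  points
}

#' Ground-truth migration trajectory for one subject and segment
#'
#' Piecewise-linear in time with a 3-month breakpoint: each DOF follows
#' `b_early * min(t, 3) + b_late * max(0, t - 3)`, zero at surgery and
#' continuous at the breakpoint. Per-subject random effects perturb the
#' population slopes.
#'
#' @param config `study_config`.
#' @param segment `"stem"` or `"cup"`.
#' @param subject_dev optional 6-vector of this subject's early-slope
#'   deviations; drawn `N(0, subject_sd^2)` when `NULL`.
#' @return A `true_trajectory`: slopes and a function `dof_at(t)`.
#' @export
true_trajectory <- function(config, segment, subject_dev = NULL) {
  if (is.null(subject_dev))
    subject_dev <- stats::rnorm(6, 0, config$subject_sd)
  b_early <- config$slope_early[[segment]] + subject_dev
  b_late <- config$slope_late[[segment]] + 0.1 * subject_dev
  structure(list(segment = segment, slope_early = b_early,
                 slope_late = b_late,
                 dof_at = function(t) {
                   stats::setNames(b_early * pmin(t, 3) +
                                     b_late * pmax(0, t - 3), dof_names)
                 }),
            class = "true_trajectory")
}

#' Generate a complete virtual follow-up study
#'
#' Builds, per subject: bone marker sets for pelvis and femur, stem and cup
#' models posed in the anatomy, ground-truth piecewise-linear migration,
#' noisy per-method implant observations at every visit, a duplicated visit
#' with random repositioning, and a planned-vs-used implant size table.
#' Left hips are exact sagittal mirrors of the right-hip construction.
#'
#' Every examination records its scene-to-scanner pose (`patient_pose`) and
#' a coarse per-implant initial pose (`init_pose`) standing in for the
#' upstream segmentation stage's rough localisation.
#'
#' @param config `study_config`.
#' @return A `study` list: `config`, `models` (stem/cup `implant_model`s),
#'   `exams` (list of examinations), `truth` (data frame of true per-visit
#'   DOF per subject and segment), `trajectories`, and `plan_table`.
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  set.seed(config$seed)
  models <- list(stem = make_implant_model("stem"),
                 cup = make_implant_model("cup"))
  # nominal implant poses in the canonical (right-hip) scene
  nominal <- list(
    stem = rigid_transform(rotation_from_cardan(2, 4, -3), c(5, -110, 3)),
    cup = rigid_transform(rotation_from_cardan(4, -3, 2), c(18, 12, -2)))
  refseg <- c(stem = "femur", cup = "pelvis")
  n_left <- round(config$prop_left * config$n_subjects)
  sides <- rep(c("left", "right"),
               c(n_left, config$n_subjects - n_left))
  exams <- list()
  truth_rows <- list()
  trajectories <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    side <- sides[s]
    pelvis <- sample_markers(config$markers_per_segment, c(25, 45, -5),
                             config$marker_spread_mm, "p")
    femur <- sample_markers(config$markers_per_segment, c(15, -70, 5),
                            config$marker_spread_mm, "f")
    traj <- list(stem = true_trajectory(config, "stem"),
                 cup = true_trajectory(config, "cup"))
    trajectories[[sid]] <- traj
    # segment frames and reference points at the true baseline pose
    frames <- list(); refpts <- list()
    for (seg in c("stem", "cup")) {
      P0 <- nominal[[seg]]
      if (seg == "stem") {
        lm <- lapply(models$stem$landmarks, function(p)
          as.numeric(transform_points(P0, rbind(p))))
        frames$stem <- build_stem_frame(lm)
      } else frames$cup <- build_table_frame()
      refpts[[seg]] <- as.numeric(
        transform_points(P0, rbind(colMeans(models[[seg]]$surface_points))))
    }
    visits <- data.frame(timepoint = config$timepoints_months, replicate = 1L)
    if (!is.na(config$double_exam_timepoint) &&
        config$double_exam_timepoint %in% config$timepoints_months)
      visits <- rbind(visits,
                      data.frame(timepoint = config$double_exam_timepoint,
                                 replicate = 2L))
    visits <- visits[order(visits$timepoint, visits$replicate), ]
    for (v in seq_len(nrow(visits))) {
      tp <- visits$timepoint[v]; rep_i <- visits$replicate[v]
      exam <- make_examination(sid, side, tp, rep_i, pelvis, femur, models,
                               nominal, frames, refpts, traj, config)
      exams[[length(exams) + 1L]] <- exam
      if (rep_i == 1L) for (seg in c("stem", "cup"))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          subject = sid, side = side, segment = seg, timepoint = tp,
          dof = dof_names, value = as.numeric(traj[[seg]]$dof_at(tp)))
    }
  }
  plan_table <- simulate_plan_table(config, sides)
  structure(list(config = config, models = models, exams = exams,
                 truth = do.call(rbind, truth_rows),
                 trajectories = trajectories, plan_table = plan_table,
                 frames_ref = refseg),
            class = "study")
}

# one examination: apply truth, per-method pose noise, mirroring, patient pose
make_examination <- function(sid, side, tp, rep_i, pelvis, femur, models,
                             nominal, frames, refpts, traj, config) {
  patient_pose <- random_rigid_transform(config$reposition_rot_deg,
                                         config$reposition_trans_mm)
  clouds <- list(); inits <- list()
  for (m in names(config$noise_sd)) {
    clouds[[m]] <- list(); inits[[m]] <- list()
    for (seg in c("stem", "cup")) {
      D <- dof_to_transform(traj[[seg]]$dof_at(tp), frames[[seg]],
                            refpts[[seg]])
      E <- dof_to_transform(stats::rnorm(6, 0, config$noise_sd[[m]]),
                            frames[[seg]], refpts[[seg]])
      pose <- compose_transforms(E, compose_transforms(D, nominal[[seg]]))
      surf <- models[[seg]]$surface_points
      keep <- sort(sample.int(nrow(surf), ceiling(0.6 * nrow(surf))))
      cl <- transform_points(pose, surf[keep, , drop = FALSE])
      if (config$point_jitter_sd > 0)
        cl <- cl + stats::rnorm(length(cl), 0, config$point_jitter_sd)
      if (side == "left") cl <- mirror_x(cl)
      cl <- transform_points(patient_pose, cl)
      clouds[[m]][[seg]] <- cl
      # coarse init: true scene pose (mirrored for left) + bounded jitter
      scene_pose <- pose
      if (side == "left") {
        M <- diag(c(-1, 1, 1))
        scene_pose <- rigid_transform(
          M %*% pose$rotation %*% mirror_model_fix(models[[seg]]),
          as.numeric(M %*% pose$translation))
      }
      jit <- random_rigid_transform(3, 4)
      inits[[m]][[seg]] <- compose_transforms(
        patient_pose, compose_transforms(jit, scene_pose))
    }
  }
  pm <- pelvis; fm <- femur
  if (tp > 0 && config$marker_instability_prob > 0) {
    for (nm in c("pm", "fm")) {
      mk <- get(nm)
      unstable <- stats::runif(nrow(mk)) < config$marker_instability_prob
      if (any(unstable))
        mk[unstable, ] <- mk[unstable, ] +
          matrix(stats::rnorm(3 * sum(unstable), 0,
                              config$marker_instability_sd), ncol = 3)
      assign(nm, mk)
    }
  }
  if (side == "left") { pm <- mirror_x(pm); fm <- mirror_x(fm) }
  pm <- transform_points(patient_pose, pm)
  fm <- transform_points(patient_pose, fm)
  list(subject = sid, side = side, timepoint = tp, replicate = rep_i,
       pelvis_markers = pm, femur_markers = fm,
       implant_clouds = clouds, init_pose = inits,
       patient_pose = patient_pose)
}

# proper rotation mapping the model onto its own sagittal mirror image:
# both models are built symmetric about their z = 0 plane, so a z-flip in
# the model frame composed with the scene mirror is a proper rotation
mirror_model_fix <- function(model) diag(c(1, 1, -1))

simulate_plan_table <- function(config, sides) {
  n <- config$n_subjects
  cup_sizes <- seq(48, 58, by = 2)
  stem_sizes <- as.character(1:9)
  variants <- c("standard", "varus", "high-offset")
  planned_cup <- sample(cup_sizes, n, replace = TRUE)
  used_cup <- ifelse(stats::runif(n) < config$plan_match_prob_cup,
                     planned_cup, planned_cup + sample(c(-2, 2), n, TRUE))
  planned_stem <- sample(stem_sizes, n, replace = TRUE)
  planned_var <- sample(variants, n, replace = TRUE)
  u <- stats::runif(n)
  used_stem <- planned_stem
  used_var <- planned_var
  size_only <- u >= config$plan_exact_prob_stem &
    u < config$plan_match_prob_stem
  miss <- u >= config$plan_match_prob_stem
  for (i in which(size_only))
    used_var[i] <- sample(setdiff(variants, planned_var[i]), 1)
  for (i in which(miss))
    used_stem[i] <- sample(setdiff(stem_sizes, planned_stem[i]), 1)
  data.frame(subject = sprintf("S%02d", seq_len(n)), side = sides,
             planned_cup_size = planned_cup, used_cup_size = used_cup,
             planned_stem_size = planned_stem,
             planned_stem_variant = planned_var,
             used_stem_size = used_stem, used_stem_variant = used_var)
}

#' Simulate a long-format migration table directly (statistical layer)
#'
#' Skips the geometric scene and draws measured migration values straight
#' from the piecewise-linear subject model plus Gaussian measurement noise:
#' `y = (b1 + u1) min(t,3) + (b2 + u2) max(0, t-3) + e`. Used for
#' mixed-model recovery and method-comparison studies where the geometry is
#' not under test.
#'
#' @param n_subjects number of subjects.
#' @param timepoints_months visit times (months).
#' @param slope_early,slope_late population slopes (units/month).
#' @param subject_sd SD of the per-subject early-slope deviation; the late
#'   deviation gets `0.1 * subject_sd`.
#' @param noise_sd residual measurement SD; a named vector gives one SD per
#'   method and one measurement per method per visit.
#' @param method_bias named additive offsets per method (default 0).
#' @param dof,segment labels stamped on the output rows.
#' @return Long data frame: subject, side, method, segment, dof,
#'   timepoint, replicate, value.
#' @export
simulate_migration_table <- function(n_subjects = 25,
                                     timepoints_months = c(0, 3, 12, 24),
                                     slope_early = 0.15, slope_late = 0.005,
                                     subject_sd = 0.05, noise_sd = 0.05,
                                     method_bias = NULL, dof = "Ty",
                                     segment = "stem") {
  methods <- names(noise_sd)
  if (is.null(methods)) { methods <- "ctrsa"; names(noise_sd) <- methods }
  if (is.null(method_bias))
    method_bias <- stats::setNames(rep(0, length(methods)), methods)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    u1 <- stats::rnorm(1, 0, subject_sd)
    u2 <- stats::rnorm(1, 0, 0.1 * subject_sd)
    mu <- (slope_early + u1) * pmin(timepoints_months, 3) +
      (slope_late + u2) * pmax(0, timepoints_months - 3)
    for (m in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), side = "right", method = m,
        segment = segment, dof = dof, timepoint = timepoints_months,
        replicate = 1L,
        value = mu + method_bias[[m]] +
          stats::rnorm(length(mu), 0, noise_sd[[m]]))
  }
  do.call(rbind, rows)
}
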