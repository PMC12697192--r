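zero_noise_config <- function(...) {
  study_config(noise_sd_ctrsa = rep(0, 6), noise_sd_mbrsa = rep(0, 6),
               ...)
}

test_that("study config validates its invariants", {
  expect_error(study_config(timepoints_months = c(0, 3, 3)), "increasing")
  expect_error(study_config(timepoints_months = c(3, 12)), "start at 0")
  expect_error(study_config(subject_sd = -1), "SDs")
  expect_error(study_config(plan_match_prob_cup = 1.2), "probabilities")
  expect_error(study_config(plan_match_prob_stem = 0.5,
                            plan_exact_prob_stem = 0.9), "exceed")
  expect_s3_class(study_config(), "study_config")
})

test_that("generate_study produces the configured cohort", {
  cfg <- study_config(n_subjects = 5, seed = 42)
  st <- generate_study(cfg)
  subjects <- unique(vapply(st$exams, function(e) e$subject, ""))
  expect_length(subjects, 5)
  # one exam per visit plus exactly one duplicated visit per subject
  for (s in subjects) {
    ex <- Filter(function(e) e$subject == s, st$exams)
    tps <- vapply(ex, function(e) e$timepoint, 0)
    reps <- vapply(ex, function(e) e$replicate, 0L)
    expect_equal(sort(unique(tps)), c(0, 3, 12, 24))
    expect_identical(sum(reps == 2L), 1L)
    expect_equal(tps[reps == 2L], 3)
  }
  expect_equal(nrow(st$plan_table), 5)
  sides <- vapply(st$exams, function(e) e$side, "")
  expect_setequal(unique(sides), c("left", "right"))
})

test_that("marker labels are stable across a subject's examinations", {
  st <- generate_study(study_config(n_subjects = 2, seed = 7))
  ex <- Filter(function(e) e$subject == "S01", st$exams)
  for (e in ex) {
    expect_identical(rownames(e$pelvis_markers),
                     rownames(ex[[1]]$pelvis_markers))
    expect_identical(rownames(e$femur_markers),
                     rownames(ex[[1]]$femur_markers))
  }
})

test_that("same config and seed give byte-identical serialized studies", {
  cfg <- study_config(n_subjects = 2, seed = 99)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(generate_study(cfg), d1)
  write_study(generate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero noise and zero slopes give geometrically frozen scenes", {
  cfg <- zero_noise_config(
    n_subjects = 2, seed = 5, subject_sd = 0,
    slope_early = list(stem = rep(0, 6), cup = rep(0, 6)),
    slope_late = list(stem = rep(0, 6), cup = rep(0, 6)))
  st <- generate_study(cfg)
  ex <- Filter(function(e) e$subject == "S01", st$exams)
  undo <- function(e, what) transform_points(
    invert_transform(e$patient_pose), e[[what]])
  base <- ex[[1]]
  for (e in ex[-1]) {
    expect_equal(undo(e, "pelvis_markers"), undo(base, "pelvis_markers"),
                 tolerance = 1e-9)
    expect_equal(undo(e, "femur_markers"), undo(base, "femur_markers"),
                 tolerance = 1e-9)
  }
})

test_that("true trajectories start at zero and are continuous at 3 months", {
  cfg <- study_config(n_subjects = 3, seed = 12)
  st <- generate_study(cfg)
  expect_true(all(st$truth$value[st$truth$timepoint == 0] == 0))
  for (tr in st$trajectories) for (seg in c("stem", "cup")) {
    f <- tr[[seg]]$dof_at
    eps <- 1e-7
    expect_equal(f(3 - eps), f(3 + eps), tolerance = 1e-5)
    # piecewise linearity: slopes match the stored parameters
    expect_equal(unname((f(3) - f(0)) / 3), tr[[seg]]$slope_early,
                 tolerance = 1e-9)
    expect_equal(unname((f(24) - f(3)) / 21), tr[[seg]]$slope_late,
                 tolerance = 1e-9)
  }
})

test_that("double-exam differences calibrate to the configured noise SD", {
  cfg <- study_config(n_subjects = 80, timepoints_months = c(0, 3),
                      noise_sd_ctrsa = rep(0.05, 6),
                      noise_sd_mbrsa = rep(0.05, 6),
                      subject_sd = 0.02, seed = 31)
  st <- generate_study(cfg)
  tab <- analyze_study(st, methods = "ctrsa", segments = "stem")
  d <- double_exam_diffs(tab)
  d <- d[d$dof %in% c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz"), ]
  sds <- tapply(d$diff, d$dof, sd)
  # each per-DOF empirical SD within sampling error of sigma * sqrt(2)
  expect_true(all(abs(sds / (0.05 * sqrt(2)) - 1) < 0.25))
  expect_lt(abs(mean(sds) / (0.05 * sqrt(2)) - 1), 0.1)
})

test_that("plan table reproduces its matching probabilities at scale", {
  cfg <- study_config(n_subjects = 500, seed = 13,
                      plan_match_prob_cup = 0.9,
                      plan_match_prob_stem = 0.8,
                      plan_exact_prob_stem = 0.6)
  sides <- rep("right", 500)
  pt <- ctrsa:::simulate_plan_table(cfg, sides)
  expect_equal(mean(pt$planned_cup_size == pt$used_cup_size), 0.9,
               tolerance = 0.05)
  expect_equal(mean(pt$planned_stem_size == pt$used_stem_size), 0.8,
               tolerance = 0.05)
  exact <- pt$planned_stem_size == pt$used_stem_size &
    pt$planned_stem_variant == pt$used_stem_variant
  expect_equal(mean(exact), 0.6, tolerance = 0.05)
})

test_that("simulate_migration_table has the declared long structure", {
  set.seed(1)
  tab <- simulate_migration_table(n_subjects = 4,
                                  noise_sd = c(ctrsa = 0.02, mbrsa = 0.05))
  expect_setequal(names(tab), c("subject", "side", "method", "segment",
                                "dof", "timepoint", "replicate", "value"))
  expect_equal(nrow(tab), 4 * 2 * 4)
  expect_true(all(tab$value[tab$timepoint == 0] != 0))   # noise at baseline
})
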