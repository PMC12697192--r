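make_long <- function(values_by_rep, dof = "Ty", timepoint = 3) {
  do.call(rbind, lapply(seq_along(values_by_rep), function(r)
    data.frame(subject = sprintf("S%02d", seq_along(values_by_rep[[r]])),
               method = "ctrsa", segment = "stem", dof = dof,
               timepoint = timepoint, replicate = r,
               value = values_by_rep[[r]])))
}

test_that("double-exam differences are replicate 2 minus replicate 1", {
  tab <- make_long(list(c(0.1, 0.2, 0.0), c(0.3, 0.2, -0.1)))
  d <- double_exam_diffs(tab)
  expect_equal(sort(d$diff), sort(c(0.2, 0, -0.1)))
  expect_equal(double_exam_diffs(make_long(list(1:4 / 10, 1:4 / 10)))$diff,
               rep(0, 4))
})

test_that("missing or extra replicates are rejected", {
  tab <- make_long(list(c(0.1, 0.2), c(0.3, 0.2)))
  expect_error(double_exam_diffs(tab[-4, ]), "missing replicate")
  tab3 <- rbind(tab, tab[3:4, ])      # duplicated replicate-2 rows
  expect_error(double_exam_diffs(tab3), "more than 2")
})

test_that("precision equals SD times the t critical value", {
  set.seed(501)
  diffs <- data.frame(method = "m", segment = "stem", dof = "Ty",
                      diff = rnorm(12, sd = 0.1))
  p <- precision_table(diffs)
  expect_equal(p$df, 11)
  expect_equal(p$precision, sd(diffs$diff) * qt(0.975, 11),
               tolerance = 1e-12)
  p2 <- precision_table(diffs, df_rule = "n")
  expect_equal(p2$precision, sd(diffs$diff) * qt(0.975, 12),
               tolerance = 1e-12)
  # scale equivariance
  diffs2 <- diffs; diffs2$diff <- diffs$diff * -3
  expect_equal(precision_table(diffs2)$precision, 3 * p$precision,
               tolerance = 1e-12)
  # all-zero differences give zero precision
  diffs0 <- diffs; diffs0$diff <- 0
  expect_equal(precision_table(diffs0)$precision, 0)
})

test_that("published precision cells recompute from their printed SDs", {
  # double-exam summary rows robust to SD rounding and df convention:
  # model-based RSA stem Ty (SD 0.10, n 12), cup Tz (SD 0.17, n 10);
  # CT-based RSA (n 14) cup Ty (SD 0.03) and stem total rotation (SD 0.11)
  expect_equal(round(precision_from_sd(0.10, 12), 2), 0.22)
  expect_equal(round(precision_from_sd(0.17, 10), 2), 0.38)
  expect_equal(round(precision_from_sd(0.03, 14), 2), 0.06)
  expect_equal(round(precision_from_sd(0.11, 14), 2), 0.24)
})

test_that("precision approaches 1.96 SD for large n", {
  set.seed(502)
  diffs <- data.frame(method = "m", segment = "s", dof = "Ty",
                      diff = rnorm(5000, sd = 0.2))
  p <- precision_table(diffs)
  expect_equal(p$t_crit, 1.96, tolerance = 1e-3)
  expect_equal(p$precision, 1.96 * p$sd_diff, tolerance = 1e-3)
})

test_that("Bland-Altman handles identity, constant offset and noise", {
  set.seed(503)
  tab <- simulate_migration_table(n_subjects = 8,
                                  noise_sd = c(a = 0, b = 0))
  ba0 <- bland_altman(tab, "a", "b")
  expect_equal(ba0$bias, 0, tolerance = 1e-12)
  expect_equal(ba0$loa_low, 0, tolerance = 1e-12)
  expect_equal(ba0$loa_high, 0, tolerance = 1e-12)
  expect_equal(ba0$n_comparisons, 8 * 3)

  tab2 <- simulate_migration_table(n_subjects = 8,
                                   noise_sd = c(a = 0, b = 0),
                                   method_bias = c(a = 0.3, b = 0))
  ba <- bland_altman(tab2, "a", "b")
  expect_equal(ba$bias, 0.3, tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 0, tolerance = 1e-12)
})

test_that("Bland-Altman recovers injected bias and LoA width", {
  set.seed(504)
  sa <- 0.08; sb <- 0.03; delta <- 0.2
  tab <- simulate_migration_table(n_subjects = 400,
                                  noise_sd = c(a = sa, b = sb),
                                  method_bias = c(a = delta, b = 0))
  ba <- bland_altman(tab, "a", "b")
  expect_equal(ba$bias, delta, tolerance = 0.05)
  expect_equal(ba$sd_diff, sqrt(sa^2 + sb^2), tolerance = 0.05)
  expect_equal(ba$loa_high - ba$bias, 1.96 * sqrt(sa^2 + sb^2),
               tolerance = 0.05)
  # bias is exactly the mean difference; LoA symmetric about it
  expect_equal(ba$bias, mean(ba$data$difference), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low,
               tolerance = 1e-12)
})

test_that("LS-means difference equals a constant method offset", {
  set.seed(505)
  tab <- simulate_migration_table(n_subjects = 10, subject_sd = 0.05,
                                  noise_sd = c(a = 0, b = 0),
                                  method_bias = c(a = 0.25, b = 0))
  ls <- suppressWarnings(lsmeans_by_timepoint(tab))
  expect_equal(ls$differences$estimate, rep(0.25, 3), tolerance = 1e-6)
  # identical methods give zero differences with CIs containing zero
  tab0 <- simulate_migration_table(n_subjects = 10, subject_sd = 0.05,
                                   noise_sd = c(a = 0.04, b = 0.04))
  tab0$value[tab0$method == "b"] <-
    tab0$value[tab0$method == "a"]
  ls0 <- suppressWarnings(lsmeans_by_timepoint(tab0))
  expect_equal(ls0$differences$estimate, rep(0, 3), tolerance = 1e-10)
  expect_error(lsmeans_by_timepoint(
    tab0[tab0$method == "a", ]), "two methods")
})

test_that("LS-means coverage: true offset inside its CI in most replicates", {
  set.seed(506)
  hit <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    tab <- simulate_migration_table(n_subjects = 10, subject_sd = 0.05,
                                    noise_sd = c(a = 0.1, b = 0.1),
                                    method_bias = c(a = 0.2, b = 0))
    ls <- suppressWarnings(suppressMessages(lsmeans_by_timepoint(tab)))
    d <- ls$differences[ls$differences$timepoint == 12, ]
    if (d$lower <= 0.2 && 0.2 <= d$upper) hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.9)
})
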