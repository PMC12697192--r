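#' Signed differences between double examinations
#'
#' For each subject and DOF at the duplicated visit, the difference
#' (replicate 2 minus replicate 1) between the two migration measurements.
#' Under the no-true-motion assumption of a double examination this
#' difference is pure measurement error.
#'
#' @param table long migration table (columns subject, method, segment,
#'   dof, timepoint, replicate, value).
#' @param timepoint the duplicated visit (months); default: the visit where
#'   replicate 2 exists.
#' @return Data frame: subject, method, segment, dof, diff.
#' @export
double_exam_diffs <- function(table, timepoint = NULL) {
  if (is.null(timepoint)) {
    tp <- unique(table$timepoint[table$replicate == 2L])
    if (length(tp) != 1L) stop("cannot infer a unique double-exam timepoint")
    timepoint <- tp
  }
  d <- table[table$timepoint == timepoint, ]
  keys <- c("subject", "method", "segment", "dof")
  r1 <- d[d$replicate == 1L, c(keys, "value")]
  r2 <- d[d$replicate == 2L, c(keys, "value")]
  if (any(duplicated(r1[keys])) || any(duplicated(r2[keys])))
    stop("more than 2 replicates at the double-exam visit")
  m <- merge(r1, r2, by = keys, suffixes = c("_1", "_2"))
  if (nrow(m) < max(nrow(r1), nrow(r2)))
    stop("missing replicate for some subjects")
  m$diff <- m$value_2 - m$value_1
  m[c(keys, "diff")]
}

#' Double-examination precision table
#'
#' Precision is the standard deviation of the double-examination
#' differences multiplied by the two-sided t critical value at the 5%
#' significance level, with degrees of freedom based on the number of
#' double examinations (`df_rule = "n-1"` by default; `"n"` available since
#' the convention is not universal).
#'
#' @param diffs output of [double_exam_diffs()], or a data frame with
#'   grouping columns and a `diff` column.
#' @param alpha significance level (two-sided).
#' @param df_rule `"n-1"` or `"n"`.
#' @return One row per (method, segment, dof): n_pairs, mean_diff, sd_diff,
#'   df, t_crit, precision.
#' @export
precision_table <- function(diffs, alpha = 0.05, df_rule = c("n-1", "n")) {
  df_rule <- match.arg(df_rule)
  keys <- intersect(c("method", "segment", "dof"), names(diffs))
  split_idx <- interaction(diffs[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(diffs, split_idx), function(g) {
    n <- nrow(g)
    if (n < 2L) stop("need at least 2 double-exam pairs per cell")
    sd_d <- stats::sd(g$diff)
    df <- if (df_rule == "n-1") n - 1L else n
    tc <- stats::qt(1 - alpha / 2, df)
    cbind(g[1, keys, drop = FALSE],
          data.frame(n_pairs = n, mean_diff = mean(g$diff), sd_diff = sd_d,
                     df = df, t_crit = tc, precision = sd_d * tc))
  }))
  rownames(out) <- NULL
  out
}

#' Precision from a printed summary SD
#'
#' The same precision formula applied to an already-summarised SD of
#' double-exam differences — the arithmetic used when recomputing a
#' published precision table from its printed SD column.
#'
#' @param sd_diff SD of double-exam differences.
#' @param n_pairs number of double examinations.
#' @inheritParams precision_table
#' @export
precision_from_sd <- function(sd_diff, n_pairs, alpha = 0.05,
                              df_rule = c("n-1", "n")) {
  df_rule <- match.arg(df_rule)
  df <- if (df_rule == "n-1") n_pairs - 1 else n_pairs
  sd_diff * stats::qt(1 - alpha / 2, df)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Pairs the two methods' measurements by subject and timepoint, computes
#' the bias (mean difference `a - b`), the SD of differences, and the
#' limits of agreement `bias +/- 1.96 SD`. Each patient followed at 3, 12
#' and 24 months contributes three comparisons; comparisons are pooled.
#'
#' @param table long migration table containing both methods.
#' @param method_a,method_b method labels; differences are `a - b`.
#' @param dof,segment which component to compare.
#' @param timepoints visits to include.
#' @return A `bland_altman` list: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n_comparisons`, and `data` (plot-ready: subject, timepoint, average,
#'   difference).
#' @export
bland_altman <- function(table, method_a = "mbrsa", method_b = "ctrsa",
                         dof = "Ty", segment = "stem",
                         timepoints = c(3, 12, 24)) {
  d <- table[table$dof == dof & table$segment == segment &
               table$replicate == 1L & table$timepoint %in% timepoints, ]
  keys <- c("subject", "timepoint")
  a <- d[d$method == method_a, c(keys, "value")]
  b <- d[d$method == method_b, c(keys, "value")]
  m <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no paired records for the two methods")
  diff <- m$value_a - m$value_b
  bias <- mean(diff)
  sd_d <- if (nrow(m) > 1L) stats::sd(diff) else 0
  structure(list(dof = dof, segment = segment, bias = bias, sd_diff = sd_d,
                 loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
                 n_comparisons = nrow(m),
                 data = data.frame(subject = m$subject,
                                   timepoint = m$timepoint,
                                   average = (m$value_a + m$value_b) / 2,
                                   difference = diff)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman %s %s: bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$segment, x$dof, x$bias, x$loa_low, x$loa_high,
              x$n_comparisons))
  invisible(x)
}

#' Least-square means per timepoint for two methods
#'
#' Repeated-measures mixed model `value ~ method * factor(timepoint) +
#' (1 | subject)` on the subjects measured with both methods; reports
#' per-timepoint LS means for each method and the method difference with
#' 95% confidence intervals.
#'
#' @param table long migration table with both methods.
#' @param dof,segment component to model.
#' @param timepoints follow-up visits to include.
#' @return List with data frames `lsmeans` (method, timepoint, lsmean,
#'   lower, upper) and `differences` (timepoint, estimate, lower, upper).
#' @export
lsmeans_by_timepoint <- function(table, dof = "Ty", segment = "stem",
                                 timepoints = c(3, 12, 24)) {
  d <- table[table$dof == dof & table$segment == segment &
               table$replicate == 1L & table$timepoint %in% timepoints, ]
  if (length(unique(d$method)) < 2L) stop("need two methods")
  d$timepoint <- factor(d$timepoint)
  d$method <- factor(d$method)
  fit <- suppressMessages(lmerTest::lmer(
    value ~ method * timepoint + (1 | subject), data = d))
  em <- emmeans::emmeans(fit, ~ method | timepoint)
  ems <- as.data.frame(em)
  ctr <- as.data.frame(stats::confint(emmeans::contrast(em, "pairwise",
                                                        by = "timepoint")))
  list(lsmeans = data.frame(method = ems$method,
                            timepoint = as.numeric(as.character(ems$timepoint)),
                            lsmean = ems$emmean,
                            lower = ems$lower.CL, upper = ems$upper.CL),
       differences = data.frame(
         timepoint = as.numeric(as.character(ctr$timepoint)),
         contrast = ctr$contrast, estimate = ctr$estimate,
         lower = ctr$lower.CL, upper = ctr$upper.CL),
       model = fit)
}
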