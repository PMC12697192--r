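#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact two-sided interval for a binomial proportion from beta
#' quantiles: lower bound the `alpha/2` quantile of `Beta(k, n - k + 1)`
#' (zero when `k = 0`), upper bound the `1 - alpha/2` quantile of
#' `Beta(k + 1, n - k)` (one when `k = n`). Reported on the percent scale;
#' rounding to integer percent happens only at report time.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level.
#' @param label optional category label.
#' @return A `concordance_result` data frame row: label, k, n,
#'   proportion_pct, ci_low_pct, ci_high_pct.
#' @export
clopper_pearson <- function(k, n, level = 0.95, label = NA_character_) {
  if (n < 1L) stop("n must be >= 1")
  if (k < 0L || k > n) stop("k must lie in [0, n]")
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  out <- data.frame(label = label, k = as.integer(k), n = as.integer(n),
                    proportion_pct = 100 * k / n,
                    ci_low_pct = 100 * lo, ci_high_pct = 100 * hi)
  class(out) <- c("concordance_result", class(out))
  out
}

#' Planned-versus-used implant size concordance
#'
#' Compares the preoperatively planned implant sizes with the ones actually
#' used, in three categories: cup size match, stem size match, and exact
#' stem match (size and offset variant — standard, varus or high-offset).
#' Each proportion gets an exact Clopper-Pearson confidence interval.
#'
#' @param plan_table data frame with one row per subject and columns
#'   `planned_cup_size`, `used_cup_size`, `planned_stem_size`,
#'   `used_stem_size`, `planned_stem_variant`, `used_stem_variant`.
#' @param level confidence level.
#' @return `concordance_result` rows for the three categories.
#' @export
plan_vs_actual <- function(plan_table, level = 0.95) {
  req <- c("planned_cup_size", "used_cup_size", "planned_stem_size",
           "used_stem_size", "planned_stem_variant", "used_stem_variant")
  miss <- setdiff(req, names(plan_table))
  if (length(miss)) stop("missing records: ", paste(miss, collapse = ", "))
  n <- nrow(plan_table)
  cup <- sum(plan_table$planned_cup_size == plan_table$used_cup_size)
  stem <- sum(plan_table$planned_stem_size == plan_table$used_stem_size)
  exact <- sum(plan_table$planned_stem_size == plan_table$used_stem_size &
                 plan_table$planned_stem_variant ==
                   plan_table$used_stem_variant)
  rbind(clopper_pearson(cup, n, level, "cup size"),
        clopper_pearson(stem, n, level, "stem size"),
        clopper_pearson(exact, n, level, "stem exact (size + variant)"))
}

#' Round a concordance table for reporting
#'
#' Half-up rounding of the percentage columns to integers, the convention
#' used when quoting agreement proportions.
#'
#' @param x `concordance_result` rows.
#' @export
report_concordance <- function(x) {
  half_up <- function(v) floor(v + 0.5)
  x$proportion_pct <- half_up(x$proportion_pct)
  x$ci_low_pct <- half_up(x$ci_low_pct)
  x$ci_high_pct <- half_up(x$ci_high_pct)
  x
}
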