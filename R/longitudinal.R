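#' Piecewise-linear design columns with a breakpoint
#'
#' The migration-over-time model uses two time covariates: time since
#' surgery `t` and the hinge `max(0, t - breakpoint)`, so the fitted mean
#' is linear on each side of the breakpoint and continuous at it. The
#' coefficient on `t` is the early slope; the coefficient on the hinge is
#' the change in slope after the breakpoint.
#'
#' @param timepoints visit times in months (>= 0).
#' @param breakpoint breakpoint in months (default 3).
#' @return Data frame with columns `t` and `hinge`.
#' @export
build_design <- function(timepoints, breakpoint = 3) {
  timepoints <- as.numeric(timepoints)
  if (any(timepoints < 0)) stop("negative time")
  data.frame(t = timepoints, hinge = pmax(0, timepoints - breakpoint))
}

#' Fit the piecewise linear mixed-effects migration model
#'
#' REML fit of `value ~ t + hinge + (1 | subject)` for one DOF: fixed
#' effects are the time since surgery and the time since the breakpoint
#' (slope change), the random effect is a per-subject intercept (random
#' slopes optionally added). Slope tests use Satterthwaite degrees of
#' freedom. The early slope is the `t` coefficient; the late slope is
#' `t + hinge`.
#'
#' @param table long migration table (one value per subject and timepoint
#'   for the chosen dof/segment/method after filtering).
#' @param dof,segment,method filters applied to `table`; pass `NULL` to
#'   skip a filter.
#' @param breakpoint months (default 3).
#' @param random_slopes if `TRUE`, adds random early/late slopes per
#'   subject.
#' @return A `piecewise_fit` list: coefficient table (`beta0`, `beta1`
#'   early slope, `beta2` slope change) with SEs, CIs and p-values,
#'   `slope_late`, variance components, fitted trajectory, and the
#'   underlying `lmerModLmerTest` object.
#' @export
fit_piecewise_lme <- function(table, dof = "Ty", segment = NULL,
                              method = NULL, breakpoint = 3,
                              random_slopes = FALSE) {
  d <- table
  if (!is.null(dof)) d <- d[d$dof == dof, ]
  if (!is.null(segment)) d <- d[d$segment == segment, ]
  if (!is.null(method)) d <- d[d$method == method, ]
  if (!is.null(d$replicate)) d <- d[d$replicate == 1L, ]
  if (nrow(d) == 0L) stop("no data after filtering")
  des <- build_design(d$timepoint, breakpoint)
  d$t <- des$t; d$hinge <- des$hinge
  if (length(unique(d$t[d$t < breakpoint + 1e-9])) < 2L ||
      length(unique(d$t[d$t > breakpoint - 1e-9])) < 2L)
    stop("need >= 2 timepoints on each side of the breakpoint")
  form <- if (random_slopes)
    value ~ t + hinge + (1 + t + hinge | subject)
  else value ~ t + hinge + (1 | subject)
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  co <- summary(fit)$coefficients
  ci <- tryCatch(suppressMessages(
    stats::confint(fit, parm = "beta_", method = "Wald")),
    error = function(e) matrix(NA_real_, 3, 2))
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- co[, "Estimate"]
  out <- list(
    dof = dof, segment = segment, method = method, breakpoint = breakpoint,
    beta0 = unname(est["(Intercept)"]),
    beta1 = unname(est["t"]),
    beta2 = unname(est["hinge"]),
    slope_late = unname(est["t"] + est["hinge"]),
    coefficients = data.frame(
      term = rownames(co), estimate = est, se = co[, "Std. Error"],
      df = co[, "df"], p_value = co[, "Pr(>|t|)"],
      lower = ci[rownames(co), 1], upper = ci[rownames(co), 2],
      row.names = NULL),
    subject_variance = sum(vc$vcov[vc$grp == "subject"]),
    residual_variance = vc$vcov[vc$grp == "Residual"],
    n_subjects = length(unique(d$subject)), n_obs = nrow(d),
    model = fit)
  tp <- sort(unique(d$t))
  out$fitted_trajectory <- data.frame(
    timepoint = tp,
    value = out$beta0 + out$beta1 * tp + out$beta2 * pmax(0, tp - breakpoint))
  class(out) <- "piecewise_fit"
  out
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "piecewise LME (%s): slope 0-%g mo = %.4f/mo, slope after = %.4f/mo\n",
    paste(c(x$segment, x$dof), collapse = " "), x$breakpoint,
    x$beta1, x$slope_late))
  print(x$coefficients, digits = 4)
  invisible(x)
}
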