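#' Fit the LQ coefficients alpha and beta from a dose-response curve
#'
#' Two-stage fit of the basic LQ model to replicate-mean surviving
#' fractions: a linearised least-squares start on
#' \eqn{-\ln \bar S_D = \alpha D + \beta D^2} (through the origin), refined
#' by nonlinear least squares on the survival scale
#' \eqn{\bar S_D = \exp(-\alpha D - \beta D^2)} with both coefficients
#' bounded below by zero. Fitting on per-condition means mirrors the usual
#' summarisation of well-replicated assays into one survival value per dose;
#' replicate scatter is reported through the residual table.
#'
#' @param table A [measurement_table] of kind `"dose_response"` with at
#'   least three distinct positive doses.
#' @return An object of class `lq_fit`: a list with `estimates`
#'   (named vector `alpha`, `beta`), `std_errors` (asymptotic, from the
#'   Jacobian at the optimum), `r_squared` (on the survival scale, against
#'   the per-dose means), `residuals` (per-condition data frame),
#'   `converged` and `status`.
#' @examples
#' f10b16 <- cell_line_params("F10B16", 0.0956, 0.0177, 0.524)
#' tab <- simulate_dose_response(f10b16, noise = noise_model(cv = 0))
#' fit_alpha_beta(tab)$estimates # recovers alpha and beta exactly
#' @export
fit_alpha_beta <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  if (table_kind(table) != "dose_response") {
    lq_abort("`table` must be a dose_response measurement table",
             "lqfrac_validation_error")
  }
  cond <- summarize_conditions(table)
  cond <- cond[cond$condition_x > 0, , drop = FALSE]
  if (nrow(cond) < 3L) {
    lq_abort("alpha/beta fitting needs at least 3 distinct positive doses",
             "lqfrac_insufficient_data")
  }

  dat <- data.frame(dose = cond$condition_x, s = cond$mean)
  # Stage 1: linearised start.
  y <- -log(dat$s)
  lin <- stats::lm(y ~ 0 + dose + I(dose^2), data = dat)
  start <- list(alpha = max(unname(stats::coef(lin)[1]), 1e-8),
                beta = max(unname(stats::coef(lin)[2]), 1e-10))
  # Stage 2: nonlinear refinement on the survival scale.
  fit <- minpack.lm::nlsLM(
    s ~ exp(-(alpha * dose + beta * dose^2)),
    data = dat, start = start, lower = c(alpha = 0, beta = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  new_lq_fit(fit, dat$s, cond, kind = "dose_response")
}

#' Estimate the sublethal-damage repair half-time from split-dose recovery
#'
#' Fits the incomplete-repair survival model for two equal fractions of dose
#' \eqn{d} separated by an interval \eqn{\Delta t},
#' \deqn{S(\Delta t) = \exp\!\left(-2\alpha d
#'   - (1+\theta)\,\beta\,(2d)^2/2\right), \quad
#'   \theta = e^{-(\ln 2 / T_{1/2})\, \Delta t},}
#' by one-parameter nonlinear least squares in \eqn{T_{1/2}}, with
#' \eqn{\alpha} and \eqn{\beta} fixed at previously fitted values. At
#' \eqn{\Delta t = 0} the curve passes exactly through the acute survival of
#' the summed dose \eqn{2d}; as \eqn{\Delta t \to \infty} it approaches two
#' independent fractions. The start value is taken from a coarse logarithmic
#' grid scan, making the 1-d fit insensitive to initialisation.
#'
#' @param table A [measurement_table] of kind `"split_dose"` (intervals in
#'   minutes) with at least three distinct intervals and a
#'   `dose_per_fraction` attribute.
#' @param alpha,beta Fixed LQ coefficients of the cell line (Gy\eqn{^{-1}},
#'   Gy\eqn{^{-2}}).
#' @return An `lq_fit` with `estimates["t_half"]` in hours; see
#'   [fit_alpha_beta()] for the other fields. A recovery series that
#'   decreases with the interval by more than the replicate noise supports
#'   triggers a non-monotonicity warning, but the fit is still attempted.
#' @export
estimate_t_half <- function(table, alpha, beta) {
  stopifnot(inherits(table, "measurement_table"))
  if (table_kind(table) != "split_dose") {
    lq_abort("`table` must be a split_dose measurement table",
             "lqfrac_validation_error")
  }
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  d <- attr(table, "dose_per_fraction", exact = TRUE)
  if (is.null(d)) {
    lq_abort("split-dose table lacks its `dose_per_fraction` attribute",
             "lqfrac_validation_error")
  }
  cond <- summarize_conditions(table)
  if (nrow(cond) < 3L) {
    lq_abort(
      "repair half-time fitting needs at least 3 distinct intervals",
      "lqfrac_insufficient_data"
    )
  }

  dat <- data.frame(dt = min_to_h(cond$condition_x), s = cond$mean)
  # Warn (and continue) if recovery decreases with the interval by more
  # than ~3 standard errors of the condition means.
  se <- cond$sd / sqrt(cond$n_replicates)
  tol <- 3 * max(se, 0, na.rm = TRUE) + 1e-12
  if (any(diff(dat$s[order(dat$dt)]) < -tol)) {
    lq_warn(
      "split-dose survival decreases with the interval beyond noise; check the measurement series",
      "lqfrac_nonmonotone_warning"
    )
  }

  model_s <- function(dt, t_half) {
    exp(-2 * alpha * d -
          2 * beta * d^2 * (1 + exp(-log(2) * dt / t_half)))
  }
  grid <- exp(seq(log(0.02), log(24), length.out = 80))
  sse <- vapply(grid, function(th) sum((dat$s - model_s(dat$dt, th))^2),
                numeric(1))
  start <- list(t_half = grid[which.min(sse)])
  fit <- minpack.lm::nlsLM(
    s ~ exp(-2 * alpha * d - 2 * beta * d^2 *
              (1 + exp(-log(2) * dt / t_half))),
    data = dat, start = start, lower = c(t_half = 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  new_lq_fit(fit, dat$s, cond, kind = "split_dose")
}

# Common packaging of an nlsLM fit into an lq_fit object.
new_lq_fit <- function(fit, observed, cond, kind) {
  est <- stats::coef(fit)
  co <- summary(fit)$coefficients
  se <- stats::setNames(co[, "Std. Error"], rownames(co))
  fitted_vals <- as.numeric(stats::fitted(fit))
  ss_res <- sum((observed - fitted_vals)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) {
    lq_warn("nonlinear fit did not converge; estimates are provisional",
            "lqfrac_convergence_warning")
  }
  structure(
    list(
      estimates = est,
      std_errors = se,
      r_squared = r2,
      residuals = data.frame(condition_x = cond$condition_x,
                             observed = observed, fitted = fitted_vals,
                             residual = observed - fitted_vals),
      converged = converged,
      status = if (converged) "converged" else "not_converged",
      kind = kind
    ),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> %s (%s)\n", x$kind, x$status))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s = %.6g +/- %.3g\n", nm, x$estimates[[nm]],
                x$std_errors[[nm]]))
  }
  cat(sprintf("  R^2 = %.6f on %d conditions\n", x$r_squared,
              nrow(x$residuals)))
  invisible(x)
}

#' Write a fit result as JSON
#'
#' Emits `{estimates, standard_errors, r_squared, status}` at full floating
#' point precision.
#'
#' @param fit An `lq_fit` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lq_fit"))
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates),
         standard_errors = as.list(fit$std_errors),
         r_squared = fit$r_squared,
         status = fit$status),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
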