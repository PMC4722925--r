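#' Surviving fraction after a single acute dose (basic LQ model)
#'
#' \deqn{S = \exp(-\alpha D - \beta D^2)} — the linear-quadratic survival
#' for instantaneous delivery, used for continuous single-fraction exposures
#' where the subfraction-based protraction models do not apply.
#'
#' @param params A [cell_line_params] object.
#' @param dose Total dose(s) \eqn{D} in Gy (\eqn{\ge 0}); vectorised.
#' @return Surviving fraction(s) in \eqn{(0, 1]}.
#' @examples
#' f10b16 <- cell_line_params("F10B16", 0.0956, 0.0177, 0.524)
#' survival_basic(f10b16, 4) # about 0.514
#' @export
survival_basic <- function(params, dose) {
  stopifnot(inherits(params, "cell_line_params"))
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    lq_abort("`dose` must be numeric and finite", "lqfrac_validation_error")
  }
  if (any(dose < 0)) {
    lq_abort("`dose` must be non-negative", "lqfrac_validation_error")
  }
  exp(-params$alpha * dose - params$beta * dose^2)
}

#' Surviving fraction for a delivery scheme under a chosen protraction model
#'
#' Evaluates the complete LQ model \eqn{S = \exp(-\alpha D - G \beta D^2)}
#' for a [fraction_scheme], dispatching the protraction factor \eqn{G} to the
#' requested formulation:
#'
#' * `"basic"`: \eqn{G = 1}; timing is ignored entirely.
#' * `"mu"`: incomplete-repair factor [g_mu()] treating subfractions as
#'   instantaneous, with the scheme's derived interval \eqn{\Delta t} as the
#'   repair interval. A single subfraction gives \eqn{G = 1} (acute dose).
#' * `"brenner"`: continuous-protraction factor [g_brenner()] with the
#'   overall treatment time as the protraction interval — the formulation
#'   deliberately ignores how the dose is split, so predictions depend on
#'   the overall time but not on the number of subfractions. For a single
#'   subfraction the actual beam-on time is used.
#' * `"keall"`: exposure-pair factor [g_keall()] with the scheme's beam-on
#'   time \eqn{\tau} and beam-off gap (see [scheme_repair_gap()]).
#'
#' @param params A [cell_line_params] object.
#' @param scheme A [fraction_scheme] object.
#' @param method One of `"mu"`, `"basic"`, `"brenner"`, `"keall"`.
#' @return An object of class `survival_prediction`: a list with fields
#'   `cell_line`, `method`, `g_value`, `survival` and `scheme`.
#' @examples
#' f10b16 <- cell_line_params("F10B16", 0.0956, 0.0177, 0.524)
#' sc <- fraction_scheme(4, 2, overall_time = 240)
#' survival_complete(f10b16, sc, method = "mu") # about 0.592
#' @export
survival_complete <- function(params, scheme,
                              method = c("mu", "basic", "brenner", "keall")) {
  stopifnot(inherits(params, "cell_line_params"),
            inherits(scheme, "fraction_scheme"))
  method <- match.arg(method)

  D <- scheme$total_dose
  n <- scheme$n_subfractions
  tau_h <- min_to_h(scheme$tau)

  g <- switch(method,
    basic = 1,
    mu = if (n == 1L) 1 else g_mu(params$mu, n, min_to_h(scheme$delta_t)),
    brenner = g_brenner(
      params$mu,
      if (n == 1L) tau_h else min_to_h(scheme$overall_time)
    ),
    keall = if (n == 1L) {
      g_brenner(params$mu, tau_h)
    } else {
      g_keall(params$mu, n, tau_h, min_to_h(scheme_repair_gap(scheme)))
    }
  )

  structure(
    list(cell_line = params$name, method = method, g_value = g,
         survival = exp(-params$alpha * D - g * params$beta * D^2),
         scheme = scheme),
    class = "survival_prediction"
  )
}

#' @export
print.survival_prediction <- function(x, ...) {
  s <- x$scheme
  cat(sprintf(
    "<survival_prediction> %s, %g Gy = %d x %.3g Gy in %.4g min\n  method = %s, G = %.5f, S = %.4f\n",
    x$cell_line, s$total_dose, s$n_subfractions, s$dose_per_subfraction,
    s$overall_time, x$method, x$g_value, x$survival
  ))
  invisible(x)
}
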