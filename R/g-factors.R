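#' Dose-protraction (Lea-Catcheside) factors
#'
#' The complete linear-quadratic model multiplies the quadratic term by a
#' dimensionless protraction factor \eqn{G \in (0, 1]} that accounts for
#' first-order repair (rate \eqn{\mu}) of sublethal lesions while the dose is
#' being delivered. Three formulations are provided, corresponding to the
#' delivery geometries they idealise:
#'
#' * `g_mu()` — incomplete-repair factor for \eqn{n} *instantaneous* equal
#'   subfractions separated by intervals \eqn{\Delta t}:
#'   \deqn{G = \frac{2}{n^2}\,\frac{\theta}{1-\theta}
#'        \left(n - \frac{1-\theta^n}{1-\theta}\right) + \frac{1}{n},
#'        \quad \theta = e^{-\mu \Delta t}.}
#'   Repair is assumed to occur only between subfractions, not during them.
#' * `g_brenner()` — continuous constant-rate delivery over an exposure time
#'   \eqn{\tau}: \deqn{G = \frac{2}{(\mu\tau)^2}
#'        \left(\mu\tau + e^{-\mu\tau} - 1\right).}
#' * `g_keall()` — \eqn{n} equal exposures of finite duration \eqn{\tau}
#'   separated by beam-off gaps \eqn{\Delta t}, i.e. repair both during and
#'   between exposures: the per-exposure kernel of `g_brenner()` averaged
#'   over exposures plus a cross-exposure term
#'   \eqn{2(\cosh\mu\tau - 1)/(\mu\tau)^2} weighted by a geometric sum in
#'   \eqn{\phi = e^{-\mu(\tau+\Delta t)}} over exposure pairs.
#'
#' All times are in hours (matching the units of the repair half-time);
#' convert schedule minutes with `x / 60`. `g_mu()` and `g_brenner()` are
#' vectorised over `delta_t` / `tau`.
#'
#' @section Limits and equivalences:
#' `g_mu(n = 1)` and `g_mu(delta_t = 0)` equal 1 (one acute dose);
#' `g_mu(delta_t -> Inf)` tends to \eqn{1/n} (fully repaired subfractions).
#' `g_brenner(tau -> 0)` equals 1. `g_keall(n = 1, ...)` reduces exactly to
#' `g_brenner()`, and for \eqn{\tau \to 0} `g_keall()` converges to
#' `g_mu()`; `g_keall()` delegates to those functions at the boundaries.
#'
#' @section Numerical notes:
#' Small arguments are handled with `expm1()` and truncated Taylor series
#' (switchover at \eqn{\mu\tau < 10^{-2}} for the continuous kernels,
#' \eqn{\mu\Delta t < 10^{-12}} for the incomplete-repair factor) so the
#' \eqn{G \to 1} limits are reached without catastrophic cancellation.
#' \eqn{\theta^n} is evaluated as `exp(-n * mu * delta_t)` so large \eqn{n}
#' cannot underflow the correction term prematurely.
#'
#' @param mu Repair rate constant in h\eqn{^{-1}} (\eqn{\mu = \ln 2/T_{1/2}}).
#' @param n Number of subfractions (integer \eqn{\ge 1}).
#' @param delta_t Interval(s) between subfractions in hours (\eqn{\ge 0}).
#'   For `g_keall()` this is the beam-off gap, so the start-to-start period
#'   is \eqn{\tau + \Delta t}.
#' @param tau Exposure (beam-on) time(s) per subfraction in hours.
#'
#' @return Numeric vector of protraction factors in \eqn{(0, 1]}.
#'
#' @examples
#' mu <- log(2) / 0.524 # F10B16 repair rate, per hour
#' g_mu(mu, n = 2, delta_t = 4)        # two well-separated 2 Gy subfractions
#' g_brenner(mu, tau = 4 / 0.81 / 60)  # 4 Gy delivered continuously
#' g_keall(mu, n = 2, tau = 2 / 0.81 / 60, delta_t = 4)
#' @name g_factors
NULL

#' @rdname g_factors
#' @export
g_mu <- function(mu, n, delta_t) {
  check_positive_scalar(mu, "mu")
  n <- check_count(n, "n")
  if (!is.numeric(delta_t) || any(!is.finite(delta_t) & !is.infinite(delta_t))) {
    lq_abort("`delta_t` must be numeric and non-missing",
             "lqfrac_validation_error")
  }
  if (any(delta_t < 0)) {
    lq_abort("`delta_t` must be non-negative", "lqfrac_validation_error")
  }
  if (n == 1L) return(rep(1, length(delta_t)))

  a <- mu * delta_t
  out <- numeric(length(a))
  small <- a < 1e-12
  out[small] <- 1 # Delta t -> 0: subfractions merge into one acute dose
  if (any(!small)) {
    aa <- a[!small]
    theta <- exp(-aa)
    om <- -expm1(-aa)      # 1 - theta, exact for small aa
    omn <- -expm1(-n * aa) # 1 - theta^n
    out[!small] <- (2 / n^2) * (theta / om) * (n - omn / om) + 1 / n
  }
  out
}

#' @rdname g_factors
#' @export
g_brenner <- function(mu, tau) {
  check_positive_scalar(mu, "mu")
  if (!is.numeric(tau) || any(!is.finite(tau))) {
    lq_abort("`tau` must be numeric and finite", "lqfrac_validation_error")
  }
  if (any(tau < 0)) {
    lq_abort("`tau` must be non-negative", "lqfrac_validation_error")
  }
  brenner_kernel(mu * tau)
}

# 2 (x + e^-x - 1) / x^2, stable near 0.
brenner_kernel <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60 + xs^4 / 360 -
    xs^5 / 2520 + xs^6 / 20160
  xl <- x[!small]
  out[!small] <- 2 * (xl + expm1(-xl)) / xl^2
  out
}

# 2 (cosh x - 1) / x^2, stable near 0.
cosh_kernel <- function(x) {
  if (x < 1e-2) {
    1 + x^2 / 12 + x^4 / 360
  } else {
    2 * (cosh(x) - 1) / x^2
  }
}

#' @rdname g_factors
#' @export
g_keall <- function(mu, n, tau, delta_t) {
  check_positive_scalar(mu, "mu")
  n <- check_count(n, "n")
  check_positive_scalar(tau, "tau", zero_ok = TRUE)
  check_positive_scalar(delta_t, "delta_t", zero_ok = TRUE)

  # The per-exposure kernel is singular at tau = 0; the instantaneous-
  # exposure factor is the exact limit, so delegate to it.
  if (tau == 0) return(g_mu(mu, n, delta_t))
  if (n == 1L) return(g_brenner(mu, tau))

  x <- mu * tau
  p <- mu * (tau + delta_t)
  phi <- exp(-p)
  omp <- -expm1(-p)                       # 1 - phi
  # sum_{k=1}^{n-1} (n - k) phi^k, via the closed geometric form
  pair_sum <- (phi / omp) * (n - (-expm1(-n * p)) / omp)
  brenner_kernel(x) / n + (2 / n^2) * cosh_kernel(x) * pair_sum
}
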