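# Independent numerical oracles for the protraction factors. These evaluate
# the defining Lea-Catcheside double integral (or its instantaneous-exposure
# pairwise sum) directly, without reusing any closed form from R/.

# G for one continuous exposure of duration tau at constant rate:
# (2/tau^2) * int_0^tau int_0^t exp(-mu (t - t')) dt' dt, by nested
# quadrature.
oracle_g_continuous <- function(mu, tau) {
  inner <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(function(tp) exp(-mu * (ti - tp)), 0, ti,
                       rel.tol = 1e-12)$value
    }, numeric(1))
  }
  2 / tau^2 *
    stats::integrate(inner, 0, tau, rel.tol = 1e-11)$value
}

# Instantaneous-exposure incomplete-repair G as the brute-force pairwise
# sum over all subfraction pairs: G = (1/n^2) sum_ij theta^|i-j|.
oracle_g_pairwise <- function(mu, n, delta_t) {
  theta <- exp(-mu * delta_t)
  idx <- seq_len(n)
  sum(theta^abs(outer(idx, idx, "-"))) / n^2
}

# Finite-exposure G for n equal exposures of duration tau separated by
# beam-off gaps delta_t, by numeric integration over every exposure pair.
# Unit dose per subfraction; D = n.
oracle_g_finite_train <- function(mu, n, tau, delta_t) {
  period <- tau + delta_t
  within <- tau^2 / 2 * oracle_g_continuous(mu, tau) # one ordered pair
  cross <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s <- (j - i) * period
        # int_0^tau int_0^tau exp(-mu (s + u - v)) du dv / tau^2, scaled
        # by rate^2 = 1/tau^2 later; compute the raw double integral here.
        inner <- function(u) {
          vapply(u, function(ui) {
            stats::integrate(function(v) exp(-mu * (s + ui - v)), 0, tau,
                             rel.tol = 1e-12)$value
          }, numeric(1))
        }
        cross <- cross +
          stats::integrate(inner, 0, tau, rel.tol = 1e-11)$value
      }
    }
  }
  # dose rate 1/tau per exposure; D = n
  (2 / n^2) * (1 / tau^2) * (n * within + cross)
}
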