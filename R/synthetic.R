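#' Multiplicative measurement-noise model for simulated survival assays
#'
#' Describes the replicate structure and noise level of a simulated
#' plate-based survival experiment: `wells_per_experiment` wells measured in
#' each of `n_experiments` independent experiments (default 7 x 3 = 21
#' replicates per condition, the design of the reference experiments).
#' Observations are the model survival multiplied by a lognormal factor with
#' mean exactly 1 and coefficient of variation `cv`; the lognormal keeps
#' simulated survivals strictly positive, and clipping at 1 (on by default)
#' reflects normalisation to the unirradiated control.
#'
#' @param cv Coefficient of variation of the multiplicative noise
#'   (fraction, \eqn{\ge 0}). The default 0.04 matches the magnitude of the
#'   replicate standard deviations in the reference survival table.
#' @param wells_per_experiment Wells per condition within one experiment.
#' @param n_experiments Number of independent experiments.
#' @param seed Optional integer seed; identical seed and configuration give
#'   bit-identical simulated tables, and the caller's RNG state is left
#'   untouched. `NULL` draws from the current RNG stream.
#' @param clip Clip simulated survivals into \eqn{(0, 1]}.
#' @return An object of class `noise_model` (a list); the total replicate
#'   count per condition is `wells_per_experiment * n_experiments`.
#' @export
noise_model <- function(cv = 0.04, wells_per_experiment = 7L,
                        n_experiments = 3L, seed = NULL, clip = TRUE) {
  check_positive_scalar(cv, "cv", zero_ok = TRUE)
  wells <- check_count(wells_per_experiment, "wells_per_experiment")
  nexp <- check_count(n_experiments, "n_experiments")
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(cv = cv, wells_per_experiment = wells, n_experiments = nexp,
         replicates = wells * nexp, seed = seed, clip = isTRUE(clip)),
    class = "noise_model"
  )
}

# Lognormal factors with E[f] = 1 and CV = cv.
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

apply_noise <- function(truth, noise) {
  r <- noise$replicates
  obs <- rep(truth, each = r) * noise_factors(length(truth) * r, noise$cv)
  if (noise$clip) obs <- pmin(obs, 1)
  obs
}

#' Simulate a replicated survival-vs-dose experiment
#'
#' Generates a dose-response [measurement_table] whose replicate survivals
#' scatter multiplicatively around the basic LQ prediction
#' [survival_basic()] at each dose. With `cv = 0` every replicate equals the
#' model value exactly, so generator and fitter can be checked against each
#' other without noise.
#'
#' @param params A [cell_line_params] object (the generating truth).
#' @param doses Positive doses in Gy; default the 2-10 Gy calibration grid.
#' @param noise A [noise_model].
#' @return A [measurement_table] of kind `"dose_response"` with an
#'   additional `experiment_id` column.
#' @examples
#' f10b16 <- cell_line_params("F10B16", 0.0956, 0.0177, 0.524)
#' tab <- simulate_dose_response(f10b16, noise = noise_model(cv = 0.05,
#'                                                           seed = 1))
#' head(tab)
#' @export
simulate_dose_response <- function(params, doses = c(2, 4, 6, 8, 10),
                                   noise = noise_model()) {
  stopifnot(inherits(params, "cell_line_params"),
            inherits(noise, "noise_model"))
  if (length(doses) == 0 || any(!is.finite(doses)) || any(doses <= 0)) {
    lq_abort("`doses` must be a non-empty vector of positive doses",
             "lqfrac_validation_error")
  }
  truth <- survival_basic(params, doses)
  obs <- maybe_with_seed(noise$seed, apply_noise(truth, noise))
  build_sim_table("dose_response", doses, obs, noise,
                  cell_line = params$name)
}

#' Simulate a split-dose recovery experiment
#'
#' Two equal fractions of dose `dose_per_fraction` separated by each
#' interval in `intervals`; replicate survivals scatter around the
#' incomplete-repair prediction
#' \eqn{S = \exp(-2\alpha d - (1+\theta)\beta(2d)^2/2)} with
#' \eqn{\theta = e^{-\mu \Delta t}}. A zero interval reduces exactly to the
#' acute survival of the summed dose.
#'
#' @param params A [cell_line_params] object.
#' @param dose_per_fraction Dose \eqn{d} in Gy of each of the two fractions.
#' @param intervals Intervals \eqn{\Delta t} in minutes (\eqn{\ge 0}).
#' @param noise A [noise_model].
#' @return A [measurement_table] of kind `"split_dose"` (condition is the
#'   interval in minutes) carrying `dose_per_fraction`.
#' @export
simulate_split_dose <- function(params, dose_per_fraction = 2,
                                intervals = c(0, 15, 30, 60, 120, 240),
                                noise = noise_model()) {
  stopifnot(inherits(params, "cell_line_params"),
            inherits(noise, "noise_model"))
  check_positive_scalar(dose_per_fraction, "dose_per_fraction")
  if (length(intervals) == 0 || any(!is.finite(intervals)) ||
      any(intervals < 0)) {
    lq_abort("`intervals` must be non-empty and non-negative",
             "lqfrac_validation_error")
  }
  d <- dose_per_fraction
  g <- g_mu(params$mu, 2L, min_to_h(intervals))
  truth <- exp(-params$alpha * 2 * d - g * params$beta * (2 * d)^2)
  obs <- maybe_with_seed(noise$seed, apply_noise(truth, noise))
  build_sim_table("split_dose", intervals, obs, noise,
                  cell_line = params$name, dose_per_fraction = d)
}

build_sim_table <- function(kind, x, obs, noise, cell_line,
                            dose_per_fraction = NULL) {
  r <- noise$replicates
  tab <- measurement_table(
    kind,
    x = rep(x, each = r),
    survival = obs,
    replicate = rep(seq_len(r), times = length(x)),
    cell_line = cell_line,
    dose_per_fraction = dose_per_fraction
  )
  tab$experiment_id <- rep(
    rep(seq_len(noise$n_experiments), each = noise$wells_per_experiment),
    times = length(x)
  )
  tab
}

#' Simulate a schedule-grid survival experiment
#'
#' Emulates a measured counterpart to a set of delivery schemes: for each
#' cell line and scheme the generating truth is the incomplete-repair
#' prediction (`method = "mu"`; single-subfraction schemes use the basic LQ
#' model, as continuous delivery is outside the subfraction models' domain),
#' perturbed by the replicate noise model and summarised as mean +/- SD per
#' condition.
#'
#' @param cell_params A list of [cell_line_params] objects.
#' @param schemes A list of [fraction_scheme] objects.
#' @param noise A [noise_model].
#' @param aggregate How the reported SD is computed: over all wells
#'   (`"wells"`, default) or over the per-experiment means
#'   (`"experiments"`). Both aggregations of the same draws are legitimate
#'   summaries of a wells-within-experiments design.
#' @return A data frame with one row per (cell line, scheme):
#'   `cell_line`, `total_dose`, `n_subfractions`, `dose_per_subfraction`,
#'   `overall_time`, `method`, `theoretical`, `experimental_mean`,
#'   `experimental_sd`.
#' @export
simulate_survival_experiment <- function(cell_params, schemes,
                                         noise = noise_model(),
                                         aggregate = c("wells",
                                                       "experiments")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(cell_params),
            all(vapply(cell_params, inherits, TRUE, "cell_line_params")),
            is.list(schemes),
            all(vapply(schemes, inherits, TRUE, "fraction_scheme")),
            inherits(noise, "noise_model"))

  run <- function() {
    rows <- list()
    for (p in cell_params) {
      for (s in schemes) {
        method <- if (s$n_subfractions == 1L) "basic" else "mu"
        truth <- survival_complete(p, s, method)$survival
        obs <- apply_noise(truth, noise)
        if (aggregate == "experiments") {
          grp <- rep(seq_len(noise$n_experiments),
                     each = noise$wells_per_experiment)
          means <- tapply(obs, grp, mean)
          m <- mean(means)
          sdev <- stats::sd(means)
        } else {
          m <- mean(obs)
          sdev <- stats::sd(obs)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = p$name, total_dose = s$total_dose,
          n_subfractions = s$n_subfractions,
          dose_per_subfraction = s$dose_per_subfraction,
          overall_time = s$overall_time, method = method,
          theoretical = truth, experimental_mean = m,
          experimental_sd = if (noise$replicates > 1) sdev else 0
        )
      }
    }
    do.call(rbind, rows)
  }
  maybe_with_seed(noise$seed, run())
}
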