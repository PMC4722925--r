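#' Define a subfractionated delivery scheme for one treatment fraction
#'
#' A fraction of total dose \eqn{D} is delivered as `n_subfractions` equal
#' beam-on segments at a constant dose rate. The constructor derives the dose
#' per subfraction \eqn{d = D/n}, the beam-on (exposure) time per subfraction
#' \eqn{\tau = d/r}, and the inter-subfraction interval \eqn{\Delta t} implied
#' by the overall treatment time under the chosen spacing convention.
#'
#' @section Spacing conventions:
#' Published schedule descriptions rarely state whether the quoted overall
#' time includes the beam-on segments, so two conventions are supported:
#'
#' * `"start_to_start"`: `overall_time` runs from the start of the first
#'   exposure to the start of the last, so \eqn{\Delta t = T/(n-1)} is the
#'   period between successive beam-on starts (and is used directly as the
#'   repair interval by the instantaneous-subfraction model).
#' * `"gap"`: `overall_time` runs from first beam-on to last beam-off, so
#'   the beam-off repair gap is \eqn{\Delta t = (T - n\tau)/(n-1)}.
#'
#' For the schedules considered here (minutes-long exposures, tens of minutes
#' between them) the two differ by at most one exposure time per interval;
#' [build_study_grid()] documents which convention reproduces the published
#' reference values for which schemes.
#'
#' @param total_dose Total dose \eqn{D} of the fraction in Gy.
#' @param n_subfractions Number of equal subfractions \eqn{n \ge 1}.
#' @param overall_time Overall treatment time \eqn{T} in minutes (see
#'   spacing conventions above). For `n_subfractions = 1` it is the delivery
#'   window and must be at least the beam-on time.
#' @param dose_rate Dose rate \eqn{r} in Gy/min. Defaults to 0.81 Gy/min,
#'   the Co-60 rate used in the reference experiments.
#' @param spacing Spacing convention, `"start_to_start"` (default) or
#'   `"gap"`.
#'
#' @return An object of class `fraction_scheme` with fields `total_dose`,
#'   `n_subfractions`, `dose_per_subfraction`, `dose_rate`, `overall_time`,
#'   `tau` (minutes), `delta_t` (minutes; `NA` for a single subfraction) and
#'   `spacing`.
#'
#' Schemes whose exposures would physically overlap (gap convention with
#' \eqn{\Delta t < 0}, start-to-start with \eqn{\Delta t < \tau}, or a single
#' subfraction with `overall_time` shorter than the beam-on time) are
#' rejected with an infeasible-schedule error.
#'
#' @examples
#' # 4 Gy in two 2 Gy subfractions, 240 min apart
#' fraction_scheme(4, 2, overall_time = 240)
#' # 4 Gy delivered continuously (about 5 min of beam-on at 0.81 Gy/min)
#' fraction_scheme(4, 1, overall_time = 5)
#' @export
fraction_scheme <- function(total_dose, n_subfractions, overall_time,
                            dose_rate = 0.81,
                            spacing = c("start_to_start", "gap")) {
  spacing <- match.arg(spacing)
  check_positive_scalar(total_dose, "total_dose")
  n <- check_count(n_subfractions, "n_subfractions")
  check_positive_scalar(overall_time, "overall_time")
  check_positive_scalar(dose_rate, "dose_rate")

  d <- total_dose / n
  tau <- d / dose_rate

  if (n == 1L) {
    if (overall_time < tau * (1 - 1e-12)) {
      lq_abort(
        sprintf(
          "infeasible schedule: overall_time (%.3f min) is shorter than the beam-on time needed to deliver %.3g Gy at %.3g Gy/min (%.3f min)",
          overall_time, total_dose, dose_rate, tau
        ),
        "lqfrac_infeasible_schedule"
      )
    }
    delta_t <- NA_real_
  } else {
    delta_t <- switch(spacing,
      start_to_start = overall_time / (n - 1),
      gap = (overall_time - n * tau) / (n - 1)
    )
    bad <- switch(spacing,
      start_to_start = delta_t < tau * (1 - 1e-12),
      gap = delta_t < -1e-12
    )
    if (bad) {
      lq_abort(
        sprintf(
          "infeasible schedule: %d exposures of %.3f min each do not fit in %.3f min under the %s convention (exposures overlap)",
          n, tau, overall_time, spacing
        ),
        "lqfrac_infeasible_schedule"
      )
    }
    delta_t <- max(delta_t, 0)
  }

  structure(
    list(total_dose = total_dose, n_subfractions = n,
         dose_per_subfraction = d, dose_rate = dose_rate,
         overall_time = overall_time, tau = tau, delta_t = delta_t,
         spacing = spacing),
    class = "fraction_scheme"
  )
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat(sprintf(
    "<fraction_scheme> %g Gy = %d x %.3g Gy @ %.3g Gy/min (%s)\n  overall time %.4g min, tau = %.4g min%s\n",
    x$total_dose, x$n_subfractions, x$dose_per_subfraction, x$dose_rate,
    x$spacing, x$overall_time, x$tau,
    if (is.na(x$delta_t)) "" else sprintf(", delta_t = %.4g min", x$delta_t)
  ))
  invisible(x)
}

#' Beam-off repair gap between consecutive subfractions
#'
#' Returns the time in minutes from the end of one exposure to the start of
#' the next, independent of the spacing convention the scheme was built with
#' (`NA` for a single subfraction). This is the interval entering the
#' exposure-pair protraction factor, whose decay argument is
#' \eqn{\mu(\tau + \Delta t_{gap})}.
#'
#' @param scheme A [fraction_scheme].
#' @return Gap in minutes.
#' @export
scheme_repair_gap <- function(scheme) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  if (scheme$n_subfractions == 1L) return(NA_real_)
  switch(scheme$spacing,
    start_to_start = scheme$delta_t - scheme$tau,
    gap = scheme$delta_t
  )
}

#' Read and write fraction schemes as JSON or CSV
#'
#' The JSON document holds one scheme with keys `total_dose_gy`,
#' `n_subfractions`, `overall_time_min`, `dose_rate_gy_per_min` and
#' `spacing` (`"start_to_start"` or `"gap"`). The CSV batch format uses the
#' same names as column headers, one scheme per row. Derived quantities
#' (dose per subfraction, `tau`, `delta_t`) are recomputed on read, so a
#' write/read round trip reproduces the scheme exactly.
#'
#' @param scheme A [fraction_scheme] (for `write_scheme()`).
#' @param schemes A list of [fraction_scheme] objects (for
#'   `write_schemes_csv()`).
#' @param path File path.
#' @return Readers return a [fraction_scheme] (JSON) or a list of them
#'   (CSV); writers return `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  jsonlite::write_json(scheme_record(scheme), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path)
  scheme_from_record(x)
}

#' @rdname write_scheme
#' @export
write_schemes_csv <- function(schemes, path) {
  stopifnot(is.list(schemes), all(vapply(schemes, inherits, TRUE,
                                         "fraction_scheme")))
  df <- do.call(rbind, lapply(schemes, function(s) {
    as.data.frame(scheme_record(s), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_schemes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("total_dose_gy", "n_subfractions", "overall_time_min",
            "dose_rate_gy_per_min", "spacing")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    lq_abort(sprintf("scheme CSV is missing column(s): %s",
                     paste(missing, collapse = ", ")),
             "lqfrac_validation_error")
  }
  lapply(seq_len(nrow(df)), function(i) scheme_from_record(df[i, ]))
}

scheme_record <- function(s) {
  list(total_dose_gy = s$total_dose, n_subfractions = s$n_subfractions,
       overall_time_min = s$overall_time,
       dose_rate_gy_per_min = s$dose_rate, spacing = s$spacing)
}

scheme_from_record <- function(x) {
  for (k in c("total_dose_gy", "n_subfractions", "overall_time_min",
              "dose_rate_gy_per_min", "spacing")) {
    if (is.null(x[[k]]) || (length(x[[k]]) == 1 && is.na(x[[k]]))) {
      lq_abort(sprintf("scheme record is missing field `%s`", k),
               "lqfrac_validation_error")
    }
  }
  fraction_scheme(as.numeric(x$total_dose_gy),
                  as.integer(x$n_subfractions),
                  as.numeric(x$overall_time_min),
                  as.numeric(x$dose_rate_gy_per_min),
                  as.character(x$spacing))
}
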