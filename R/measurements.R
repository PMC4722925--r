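#' Replicated survival-fraction measurements
#'
#' A `measurement_table` holds replicated surviving-fraction observations
#' keyed by an experimental condition: the dose in Gy for a dose-response
#' curve (`kind = "dose_response"`) or the interval between two equal split
#' doses in minutes (`kind = "split_dose"`). Survival values are fractions of
#' the unirradiated control, so they must lie in \eqn{(0, 1]}; the implicit
#' zero-dose point \eqn{S(0) = 1} is not stored.
#'
#' @param kind `"dose_response"` or `"split_dose"`.
#' @param x Condition values: dose in Gy, or split interval in minutes.
#'   Recycled against `survival` by condition when `survival` is grouped per
#'   condition; otherwise supply one `x` per observation.
#' @param survival Surviving fractions in \eqn{(0, 1]}, one per observation.
#' @param replicate Optional replicate identifiers (defaults to a counter
#'   within each condition).
#' @param cell_line Optional cell-line label stored as an attribute.
#' @param dose_per_fraction For split-dose tables: the dose \eqn{d} in Gy of
#'   each of the two fractions (required by [estimate_t_half()]).
#'
#' @return A data frame of class `measurement_table` with columns
#'   `condition_x`, `replicate_id`, `survival`, plus attributes `kind`,
#'   `cell_line` and `dose_per_fraction`.
#' @export
measurement_table <- function(kind = c("dose_response", "split_dose"),
                              x, survival, replicate = NULL,
                              cell_line = NA_character_,
                              dose_per_fraction = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(x) || !is.numeric(survival)) {
    lq_abort("`x` and `survival` must be numeric", "lqfrac_validation_error")
  }
  if (length(x) != length(survival)) {
    lq_abort("`x` and `survival` must have the same length",
             "lqfrac_validation_error")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    lq_abort("`x` must be finite and non-negative",
             "lqfrac_validation_error")
  }
  if (any(!is.finite(survival)) || any(survival <= 0) || any(survival > 1)) {
    lq_abort("`survival` values must lie in (0, 1]",
             "lqfrac_validation_error")
  }
  if (kind == "split_dose") {
    if (is.null(dose_per_fraction)) {
      lq_abort("split-dose tables require `dose_per_fraction`",
               "lqfrac_validation_error")
    }
    check_positive_scalar(dose_per_fraction, "dose_per_fraction")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(x), x, FUN = seq_along)
  }
  out <- data.frame(condition_x = x, replicate_id = replicate,
                    survival = survival)
  structure(out,
            kind = kind, cell_line = cell_line,
            dose_per_fraction = dose_per_fraction,
            class = c("measurement_table", "data.frame"))
}

table_kind <- function(table) attr(table, "kind", exact = TRUE)

# Per-condition replicate means in condition order, as a data frame.
summarize_conditions <- function(table) {
  f <- factor(table$condition_x) # numeric uniques sort numerically
  data.frame(
    condition_x = as.numeric(levels(f)),
    n_replicates = as.integer(tapply(table$survival, f, length)),
    mean = as.numeric(tapply(table$survival, f, mean)),
    sd = as.numeric(tapply(table$survival, f, stats::sd))
  )
}

#' Read and write measurement tables as CSV
#'
#' The CSV dialect has a mandatory header with columns `condition_x`,
#' `replicate_id` and `survival` (extra columns are preserved on read and
#' ignored by the fitters).
#'
#' @param table A [measurement_table].
#' @param path File path.
#' @inheritParams measurement_table
#' @return `read_measurements_csv()` returns a [measurement_table];
#'   `write_measurements_csv()` returns `path` invisibly.
#' @export
write_measurements_csv <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path, kind = c("dose_response",
                                                 "split_dose"),
                                  cell_line = NA_character_,
                                  dose_per_fraction = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_x", "replicate_id", "survival")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    lq_abort(sprintf("measurement CSV is missing column(s): %s",
                     paste(missing, collapse = ", ")),
             "lqfrac_validation_error")
  }
  measurement_table(kind, df$condition_x, df$survival,
                    replicate = df$replicate_id, cell_line = cell_line,
                    dose_per_fraction = dose_per_fraction)
}
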