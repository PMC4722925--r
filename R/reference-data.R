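#' Published radiobiological parameters of the two reference cell lines
#'
#' Loads the bundled parameter set for the F10B16 skin melanoma and 4T1
#' breast adenocarcinoma cell lines: LQ coefficients fitted from 2-10 Gy
#' dose-response curves and sublethal-repair half-times from split-dose
#' recovery (F10B16: alpha = 0.0956 /Gy, beta = 0.0177 /Gy^2,
#' T1/2 = 0.524 h; 4T1: alpha = 0.0424 /Gy, beta = 0.0399 /Gy^2,
#' T1/2 = 0.344 h).
#'
#' @return A named list of [cell_line_params] objects (`F10B16`, `4T1`).
#' @export
reference_cell_params <- function() {
  df <- utils::read.csv(
    system.file("extdata", "cell_parameters.csv", package = "lqfrac"),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(df)), function(i) {
    cell_line_params(df$cell_line[i], df$alpha[i], df$beta[i],
                     df$t_half_h[i])
  })
  stats::setNames(out, df$cell_line)
}

#' Published 4 Gy survival reference table
#'
#' The measured (MTT assay, mean +/- SD over 7 wells x 3 experiments) and
#' calculated (incomplete-repair model; basic LQ for the continuous row)
#' surviving fractions for a total dose of 4 Gy delivered as 1, 2, 4 or 8
#' subfractions over overall treatment times of 5-240 minutes, for both
#' reference cell lines.
#'
#' @return A data frame with columns `cell_line`, `n_subfractions`,
#'   `dose_per_subfraction`, `overall_time` (minutes), `experimental_mean`,
#'   `experimental_sd`, `theoretical_mean`, `theoretical_sd`.
#' @export
reference_survival_table <- function() {
  utils::read.csv(
    system.file("extdata", "survival_reference_4gy.csv",
                package = "lqfrac"),
    stringsAsFactors = FALSE
  )
}
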