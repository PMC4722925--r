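# Shared fixtures: the two reference cell lines, built in code.

f10b16 <- cell_line_params("F10B16", alpha = 0.0956, beta = 0.0177,
                           t_half = 0.524)
t4_1 <- cell_line_params("4T1", alpha = 0.0424, beta = 0.0399,
                         t_half = 0.344)

noiseless <- function(wells = 1L, experiments = 1L) {
  noise_model(cv = 0, wells_per_experiment = wells,
              n_experiments = experiments)
}
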