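cell_line,alpha,beta,t_half_h,t_half_se_h
F10B16,0.0956,0.0177,0.524,0.035
4T1,0.0424,0.0399,0.344,0.015
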