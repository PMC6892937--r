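# Canonical parameter set of the stochastic E-I (PING) network.
# Rates are per ms; synaptic strengths and inputs are dimensionless.
alpha_E: 0.1
alpha_I: 0.2
beta_E: 1
beta_I: 2
h_E: -3.8
h_I: -8
W_ee: 27.4
W_ii: 1.3
W_ei: 26.3
W_ie: 32
N_E: 800
N_I: 200
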