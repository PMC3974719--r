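# Flatfish-like stock: fast-growing, long-lived pleuronectid.
name; "flatfish"
ages; seq(0, 20, by = 1)
years; seq(1980, 2012, by = 1)
M; 0.22
Linf; 50
k; 0.3
t0; -0.3
w_alpha; 8.0e-6
w_beta; 3.05
mat_a50; 3
mat_slope; 1.5
h; 0.65
R0; 2e6
sigma_R; 0.4
cv_length; 0.1
length_bins; seq(6, 64, by = 2)
fleets; c(1, 2)
fleet1_kind; "fishery"
fleet1_sel_a50; 3.5
fleet1_sel_slope; 1.4
fleet1_timing; 0.5
fleet2_kind; "survey"
fleet2_sel_a50; 2
fleet2_sel_slope; 1.5
fleet2_q; 1
fleet2_timing; 0.5
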