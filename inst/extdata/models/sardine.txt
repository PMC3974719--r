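# Sardine-like stock: fast-growing, short-lived small pelagic.
name; "sardine"
ages; seq(0, 8, by = 1)
years; seq(1988, 2012, by = 1)
M; 0.4
Linf; 25
k; 0.4
t0; -0.5
w_alpha; 7.0e-6
w_beta; 3.0
mat_a50; 1.5
mat_slope; 2
h; 0.65
R0; 5e8
sigma_R; 0.4
cv_length; 0.1
length_bins; seq(8, 30, by = 1)
fleets; c(1, 2)
fleet1_kind; "fishery"
fleet1_sel_a50; 2
fleet1_sel_slope; 2
fleet1_timing; 0.5
fleet2_kind; "survey"
fleet2_sel_a50; 1.2
fleet2_sel_slope; 2
fleet2_q; 1
fleet2_timing; 0.5
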