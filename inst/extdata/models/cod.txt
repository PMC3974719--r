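# Cod-like stock: slow-growing, long-lived demersal gadoid.
# Key; value dialect, see SCHEMA.md in this folder.
name; "cod"
ages; seq(0, 25, by = 1)
years; seq(1974, 2012, by = 1)
M; 0.2
Linf; 120
k; 0.1
t0; -0.2
w_alpha; 6.8e-6
w_beta; 3.1
mat_a50; 4
mat_slope; 1.2
h; 0.65
R0; 1e6
sigma_R; 0.4
cv_length; 0.1
length_bins; seq(10, 150, by = 5)
fleets; c(1, 2)
fleet1_kind; "fishery"
fleet1_sel_a50; 4.5
fleet1_sel_slope; 1.1
fleet1_timing; 0.5
fleet2_kind; "survey"
fleet2_sel_a50; 2.5
fleet2_sel_slope; 1.2
fleet2_q; 1
fleet2_timing; 0.5
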