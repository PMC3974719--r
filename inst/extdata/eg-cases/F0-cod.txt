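pattern; "ramp_constant"
f_max; 0.13
ramp_years; 20
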