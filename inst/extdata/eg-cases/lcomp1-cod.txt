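fleets; c(1, 2)
years; list(seq(1994, 2012, by = 2), seq(1994, 2012, by = 2))
Nsamp; list(50, 50)
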