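fleets; 2
years; list(seq(1974, 2012, by = 2))
sds_obs; list(0.1)
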