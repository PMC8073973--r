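width_angstrom,volume_cm3_per_g
35,0.03
60,0.06
100,0.10
180,0.14
300,0.10
450,0.05
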