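# Example scenario: hydrolysis of the synthetic beech substrate at full
# surface-coverage stoichiometry (e_l = 1) and 2 percent dry matter.
substrate:
  path: beech_synthetic.yaml
e_l: 1
b_l: 0.02
times_min: [30, 60, 120, 360, 600, 1440]
n: 50
params:
  M_p: 755
  tau: 2
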