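# Synthetic example substrate: dilute-acid pretreated beech-like particle,
# 400 um diameter, ~24 m2/g enzyme-accessible surface. Units: cm, g, cm3;
# pore widths in Angstrom, specific volumes in cm3 per g dry substrate
# (incremental bins). Not measured data.
label: beech_synthetic
radius_cm: 0.02
apparent_density_g_cm3: 0.8
cellulose_fraction: 0.55
digestibility: 0.8
cellulose_density_g_cm3: 1.5
psd:
- width_angstrom: 35.0
  volume_cm3_per_g: 0.0165
- width_angstrom: 60.0
  volume_cm3_per_g: 0.033
- width_angstrom: 100.0
  volume_cm3_per_g: 0.055
- width_angstrom: 180.0
  volume_cm3_per_g: 0.077
- width_angstrom: 300.0
  volume_cm3_per_g: 0.055
- width_angstrom: 450.0
  volume_cm3_per_g: 0.0275
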