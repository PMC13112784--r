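# Interaction criteria overrides.  Absent keys keep the built-in
# defaults (distances in Angstrom, angles in degrees).
vdw_buffer: 1.0
hb_ele_cutoff: 3.2
rules:
  CH_O:
    ha_max: 3.22
    angle_min: 94.58
  CH_PI:
    buffer: 1.0
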