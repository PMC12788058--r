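# Default Kretschmann sensing stack: SF11-type prism (constant index),
# 2 nm chromium adhesion layer, 48 nm gold film, aqueous analyte.
incident_angle_deg: 51.2
layers:
  - name: prism
    thickness_nm: semi_infinite
    dispersion: {type: constant, "n": 1.785}
  - name: chromium
    thickness_nm: 2
    dispersion: {type: builtin, name: chromium_synthetic}
  - name: gold
    thickness_nm: 48
    dispersion: {type: builtin, name: gold_jc}
  - name: analyte
    thickness_nm: semi_infinite
    dispersion: {type: constant, "n": 1.333}
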