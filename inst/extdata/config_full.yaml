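# Calibrated full-profile baseline: 5000 x 1000 um gut strip, E14.5-E17.5.
# These are the package defaults, written out for reference and editing.
profile: full
dt_min: 1.0
environment:
  width_um: 5000.0
  height_um: 1000.0
  lto_count: 12
  lto_radius_um: 10.0
cells:
  motile_radius_um: 5.0
  speed_um_per_min: 5.0
adhesion:
  r_adh_um: 15.0
  l0: 0.2
  dl: 0.005
chemokine:
  r_chem_um: 200.0
  threshold: 0.3
  fd_step_um: 1.0
input:
  form: linear
  fraction_pct: 0.45
  fold: 1.0
  k_per_hour: 0.028881132523331052
  t_end_hours: 72.0
  lti_form: linear
  lti_fraction_pct: 0.45
patches:
  linking_distance_um: 20.0
  min_size: 5
  basis: cells
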