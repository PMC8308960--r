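model:
  D_fd:
    value: 5000.0
    unit: 1/h
  Jmax_pgp:
    value: 0.0
    unit: pmol/h per 1e6 cells
  Kd_pgp:
    value: 1000.0
    unit: nM
  k_tubulin_on:
    value: 0.12406
    unit: 1/(nM h)
  k_tubulin_off:
    value: 0.6203
    unit: 1/h
  B_tubulin_max:
    value: 30010.0
    unit: nM
  k_formation_free:
    value: 271.3
    unit: 1/h
  k_formation_tubulin:
    value: 0.3056
    unit: 1/h
  k_release:
    value: 0.9811
    unit: 1/h
  Jmax_inter_exo:
    value: 266.5
    unit: pmol/h per 1e6 cells
  Kd_inter_exo:
    value: 38.23
    unit: nM
  fu_medium:
    value: 0.1568
    unit: fraction
  V_medium:
    value: 0.002
    unit: L
  v_cell:
    value: 2.0e-12
    unit: L
  N0:
    value: 1000000.0
    unit: cells
  reuptake_to: cytosol
  alpha_targets: both
  provenance: calibrated
pd:
  k_kill:
    value: 0.045
    unit: 1/h
  EC50_initial:
    value: 60000.0
    unit: nM
  gamma_EC50:
    value: 0.018
    unit: 1/h
  n_hill:
    value: 1.5
    unit: dimensionless
  k_g:
    value: 0.02
    unit: 1/h
  ec50_floor:
    value: 1.0
    unit: nM
  ec50_form: exponential
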