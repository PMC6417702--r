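# Generic two-nucleus radical pair: one spin-1/2 nucleus per radical,
# a2 fixed at 1.0 mT. Units are explicit in every key.
system:
  g: [2.0, 2.0]
  eta_mT: 0.0
  nuclei:
    - label: n1
      radical: 1
      spin: 0.5
      a_mT: 0.5
    - label: n2
      radical: 2
      spin: 0.5
      a_mT: 1.0
fields:
  B0_uT: 50.0
  B1_uT: 50.0
  nu_MHz: 0.0
  phi_rad: 0.0
  polarization: circular
rates:
  kS_per_s: 1.0e+06
  kT_per_s: 1.0e+06
scan:
  nu_min_MHz: 0.0
  nu_max_MHz: 50.0
  nu_step_MHz: 0.1
ensemble:
  n_alpha: 8
  n_beta: 8
  n_gamma: 8
  'N': 1
seed: 1
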