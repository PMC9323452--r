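vital_rates:
  config:
    active_params:
    - phi_j
    - phi_ad
    - pi
    age_breaks:
      phi:
      - 1
      - 2
      psi: 1
      pi: 1
      omega: 1
      p: 1
    bs_effects_on: []
    productivity_family: fixed_one
    correlation_type: 1
    pre_breeder: no
    breeding_from_age: 1
    detection_year_effect: yes
  mu:
    phi: 0.6190392
    pi: 0.4054651
    p: 2.1972246
  age_effects:
    phi:
    - 0.0
    - 0.4795731
    psi: 0.0
    pi: 0.0
    omega: 0.0
    p: 0.0
  bs_effects: {}
  sigma_omega_resid: ~
covariance:
  sigma:
    phi_j: 0.4
    phi_ad: 0.4
    pi: 0.4
  corr:
    phi_j:
      phi_j: 1.0
      phi_ad: 0.6
      pi: 0.24
    phi_ad:
      phi_j: 0.6
      phi_ad: 1.0
      pi: 0.4
    pi:
      phi_j: 0.24
      phi_ad: 0.4
      pi: 1.0
  sigma_p: 0.1
design:
  n_years: 10.0
  recruits_per_year: 15.0
  seed: 2024.0
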