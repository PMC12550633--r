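temperature_K: 300.0
cofactors:
- id: W1
  role: bifurcation_site
  pathway: bifurcation
  potential_V: 1.1
- id: W2
  role: bifurcation_site
  pathway: bifurcation
  potential_V: 1.1
- id: WH1
  role: relay
  pathway: hot
  potential_V: 1.9
- id: WH2
  role: relay
  pathway: hot
  potential_V: 1.75
- id: Thot
  role: terminus
  pathway: hot
  potential_V: 1.6
- id: WL1
  role: relay
  pathway: cold
  potential_V: 1.1
- id: WL2
  role: relay
  pathway: cold
  potential_V: 1.05
- id: Tcold
  role: terminus
  pathway: cold
  potential_V: 1.0
edges:
- from: W1
  to: WH1
  distance_A: 5.0
- from: WH1
  to: WH2
  distance_A: 5.0
- from: WH2
  to: Thot
  distance_A: 5.0
- from: W2
  to: WL1
  distance_A: 10.0
- from: WL1
  to: WL2
  distance_A: 5.0
- from: WL2
  to: Tcold
  distance_A: 5.0
interactions:
- site_a: W1
  site_b: W2
  epsilon_eV: 1.6
rate_params:
  lambda_outer_eV: 0.9
  hbar_omega_eV: 0.15
  huang_rhys: 0.5
  beta_invA: 0.6
  V0_eV: 0.01
  n_max: 100
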