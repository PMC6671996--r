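parameters:
  k_p1: 3.0
  K_p1: 0.3
  k_p2: 1.0
  K_p2: 0.4
  k_p3: 1.0
  V_d1: 1.5
  K_d1: 0.05
  V_d2: 1.0
  K_d2: 0.05
  V_d3: 0.9
  K_d3: 0.05
  k_syn_GRm: 1.0
  IC50_GRm: 0.4
  k_deg: 0.12
  k_syn_GR: 0.8
  k_deg_GR: 0.1
  k_on: 0.05
  k_T: 0.8
  k_re: 0.8
  r_f: 0.5
  k_t: 2.0
  k_us: 3.0
  K_M_us: 0.6
  'n': 5.0
  k_deg_us: 1.0
  k_eff: 2.0
schedule:
  lights_on: 7.0
  lights_off: 21.0
  period: 24.0
  amplitude: 1.0
  light_deg_signal: dark
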