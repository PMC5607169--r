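microtubules:
  R: 3.0
  v_plus: 0.018
  v_minus: 0.045
  r_cat: 0.0078
  r_res: 0.0016
  r_nuc: 0.05
  M: 100
feedback:
  r_u0: 0.010224501834401
  r_uinf: 0.00102245018344
  p: 5.0
  c_star_full_circle: 20000.0
polarity_factor:
  v_m: 0.81
  k_u: 0.07
  D: 0.02
  d_is_angular: yes
  l_half: 15.0
  C_total: 37000
simulation:
  dt: 1.0
  t_total: 20000.0
  t_equil: 10000.0
  seed: 1.0
  mode: normal
  record_interval: 20.0
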