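# Default stenosis channel at one operating point
geometry:
  X0_um: 200
  Y0_um: 100
  Z0_um: 130
  S: 0.8
  alpha_deg: 85
  placement: eccentric
  fillet_um: 6
fluid:
  name: blood_newtonian
operating:
  gamma0_s_inv: 1000
  f_Hz: 2
solver:
  nx: 192
  ny: 48
  tol: 1.0e-7
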