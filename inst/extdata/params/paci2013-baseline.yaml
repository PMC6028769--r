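# Pre-calibration baseline: membrane-current parameters of the 2013 hiPSC-CM
# ventricular model family (with the late Na+ current of the 2015 update) and
# ryanodine-receptor constants seeded from the human atrial three-gate RyR
# formulation, rescaled to 1/10 of their source values to match this model's
# cytosolic Ca2+ scale. This set is the starting point of the biomarker-range
# parameter optimization.
# Units as in paci2018-optimized.yaml.
name: paci2013-baseline
description: >-
  Baseline (original) values of the optimized parameter subset, with
  supplementary-derived RyR gate slopes and time constants; all other
  parameters identical to the calibrated set.
parameters:
  Cm: 9.87109e-11
  Vc: 8800.0
  V_SR: 583.73
  Na_o: 151.0
  K_o: 5.4
  Ca_o: 1.8
  K_i: 150.0
  G_Na: 3671.2302
  G_CaL: 8.635702e-5
  G_Kr: 29.8667
  G_Ks: 2.041
  G_K1: 28.1492
  G_f: 30.10312
  G_to: 29.9038
  G_bNa: 0.95
  G_bCa: 0.727272
  G_pCa: 0.4125
  K_pCa: 0.0005
  I_NaK_max: 2.2958
  Km_K: 1.0
  Km_Na: 40.0
  I_NaCa_max: 5978.0
  Km_Ca: 1.38
  Km_Nai: 87.5
  K_sat: 0.1
  gamma: 0.35
  alpha: 2.8571432
  G_NaL: 17.25
  Vh_hL: 87.61
  tau_hL: 0.2
  V_max_up: 0.56064
  K_up: 2.5e-4
  I_leak_max: 4.444e-4
  I_rel_max: 62.5
  RyR_a1: 0.0505
  RyR_a2: 0.0427
  RyR_a_half: 0.029
  RyR_o_half: 0.022
  RyR_c_half: 0.001
  RyR_a_k: 0.0082
  RyR_o_k: 0.003
  RyR_c_k: 0.002
  tau_RyR_a: 1.0
  tau_RyR_o: 0.01875
  tau_RyR_c: 0.0875
  E_f: -0.017
  P_kNa: 0.03
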