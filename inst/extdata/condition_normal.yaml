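name: normal
family: biphasic
dopamine:
  alpha_dop: 0.8
  alpha_normal: 0.8
  phi: 0.0
neurons:
  D1-SPN:
    model: lif
    C_m: 192.0
    g_L: 8.039999999999999
    E_L: -87.200000000000003
    V_th: -45.0
    V_reset: -87.200000000000003
    E_ex: 0.0
    E_in: -64.0
    tau_syn_ex: 0.3
    tau_syn_in: 2.0
    I_e: 128.0
    t_ref: 2.0
    beta_EL: 0.05
    beta_Vth: 0.205
  D2-SPN:
    model: lif
    C_m: 157.0
    g_L: 6.46
    E_L: -85.400000000000006
    V_th: -45.0
    V_reset: -85.400000000000006
    E_ex: 0.0
    E_in: -64.0
    tau_syn_ex: 0.3
    tau_syn_in: 2.0
    I_e: 0.0
    t_ref: 2.0
    beta_EL: 0.0
    beta_Vth: 0.0
  FSI:
    model: lif
    C_m: 700.0
    g_L: 16.670000000000002
    E_L: -65.0
    V_th: -54.0
    V_reset: -65.0
    E_ex: 0.0
    E_in: -76.0
    tau_syn_ex: 0.3
    tau_syn_in: 2.0
    I_e: 0.0
    t_ref: 2.0
    beta_EL: -0.078
    beta_Vth: 0.0
  STN:
    model: lif
    C_m: 60.0
    g_L: 10.0
    E_L: -80.200000000000003
    V_th: -64.0
    V_reset: -70.0
    E_ex: -10.0
    E_in: -84.0
    tau_syn_ex: 0.33
    tau_syn_in: 1.5
    I_e: 1.0
    t_ref: 2.0
    beta_EL: 0.0
    beta_Vth: 0.0
  GPe-TA:
    model: adex
    C_m: 60.0
    g_L: 1.0
    E_L: -55.100000000000001
    V_th: -54.700000000000003
    V_reset: -60.0
    E_ex: 0.0
    E_in: -65.0
    tau_syn_ex: 1.0
    tau_syn_in: 5.5
    I_e: 1.0
    t_ref: 2.0
    a: 2.5
    b: 105.0
    Delta_T: 2.55
    tau_w: 20.0
    V_peak: 0.0
    beta_EL: -0.181
    beta_Vth: 0.0
  GPe-TI:
    model: adex
    C_m: 40.0
    g_L: 1.0
    E_L: -55.100000000000001
    V_th: -54.700000000000003
    V_reset: -60.0
    E_ex: 0.0
    E_in: -65.0
    tau_syn_ex: 4.8
    tau_syn_in: 1.0
    I_e: 12.0
    t_ref: 2.0
    a: 2.5
    b: 70.0
    Delta_T: 1.7
    tau_w: 20.0
    V_peak: 0.0
    beta_EL: -0.181
    beta_Vth: 0.0
  SNr:
    model: adex
    C_m: 80.0
    g_L: 3.0
    E_L: -55.799999999999997
    V_th: -55.200000000000003
    V_reset: -65.0
    E_ex: 0.0
    E_in: -80.0
    tau_syn_ex: 5.7
    tau_syn_in: 2.04
    I_e: 0.0
    t_ref: 2.0
    a: 3.0
    b: 200.0
    Delta_T: 1.6
    tau_w: 20.0
    V_peak: 0.0
    beta_EL: -0.0896
    beta_Vth: 0.0
projections:
  D1-SPN->D1-SPN:
    source: D1-SPN
    target: D1-SPN
    K: 364
    weight: -0.15
    delay: 1.7
    beta_bi: 0.88
    beta_tri: 0.88
    beta: 0.88
    weight_normal: -0.15
  D1-SPN->D2-SPN:
    source: D1-SPN
    target: D2-SPN
    K: 84
    weight: -0.375
    delay: 1.7
    beta_bi: 0.88
    beta_tri: 0.88
    beta: 0.88
    weight_normal: -0.375
  D2-SPN->D1-SPN:
    source: D2-SPN
    target: D1-SPN
    K: 392
    weight: -0.45
    delay: 1.7
    beta_bi: 0.88
    beta_tri: 0.88
    beta: 0.88
    weight_normal: -0.45
  D2-SPN->D2-SPN:
    source: D2-SPN
    target: D2-SPN
    K: 504
    weight: -0.35
    delay: 1.7
    beta_bi: 0.88
    beta_tri: 0.88
    beta: 0.88
    weight_normal: -0.35
  FSI->D1-SPN:
    source: FSI
    target: D1-SPN
    K: 16
    weight: -2.6
    delay: 1.7
    beta_bi: 0.0
    beta_tri: 0.0
    beta: 0.0
    weight_normal: -2.6
  FSI->D2-SPN:
    source: FSI
    target: D2-SPN
    K: 11
    weight: -2.6
    delay: 1.7
    beta_bi: -0.9
    beta_tri: -0.9
    beta: -0.9
    weight_normal: -2.6
  GPe-TA->D1-SPN:
    source: GPe-TA
    target: D1-SPN
    K: 10
    weight: -0.02
    delay: 7.0
    beta_bi: -1.22
    beta_tri: -1.22
    beta: -1.22
    weight_normal: -0.02
  GPe-TA->D2-SPN:
    source: GPe-TA
    target: D2-SPN
    K: 10
    weight: -0.04
    delay: 7.0
    beta_bi: -1.15
    beta_tri: -1.15
    beta: -1.15
    weight_normal: -0.04
  FSI->FSI:
    source: FSI
    target: FSI
    K: 10
    weight: -0.4
    delay: 1.7
    beta_bi: -1.27
    beta_tri: -1.27
    beta: -1.27
    weight_normal: -0.4
  GPe-TA->FSI:
    source: GPe-TA
    target: FSI
    K: 10
    weight: -0.25
    delay: 7.0
    beta_bi: -0.53
    beta_tri: -0.53
    beta: -0.53
    weight_normal: -0.25
  GPe-TI->FSI:
    source: GPe-TI
    target: FSI
    K: 10
    weight: -1.0
    delay: 7.0
    beta_bi: -0.53
    beta_tri: -0.53
    beta: -0.53
    weight_normal: -1.0
  GPe-TI->SNr:
    source: GPe-TI
    target: SNr
    K: 32
    weight: -52.5
    delay: 3.0
    beta_bi: 0.0
    beta_tri: 0.0
    beta: 0.0
    weight_normal: -52.5
  D1-SPN->SNr:
    source: D1-SPN
    target: SNr
    K: 500
    weight: -15.0
    delay: 7.0
    beta_bi: 0.42
    beta_tri: 0.56
    beta: 0.42
    weight_normal: -15.0
  STN->SNr:
    source: STN
    target: SNr
    K: 30
    weight: 4.78
    delay: 4.0
    beta_bi: 0.0
    beta_tri: 0.0
    beta: 0.0
    weight_normal: 4.78
  D2-SPN->GPe-TI:
    source: D2-SPN
    target: GPe-TI
    K: 500
    weight: -1.08
    delay: 7.0
    beta_bi: -1.0
    beta_tri: -0.48
    beta: -1.0
    weight_normal: -1.08
  STN->GPe-TA:
    source: STN
    target: GPe-TA
    K: 30
    weight: 0.24
    delay: 2.0
    beta_bi: -0.3
    beta_tri: -0.3
    beta: -0.3
    weight_normal: 0.24
  STN->GPe-TI:
    source: STN
    target: GPe-TI
    K: 30
    weight: 0.175
    delay: 2.0
    beta_bi: -0.3
    beta_tri: -0.3
    beta: -0.3
    weight_normal: 0.175
  GPe-TA->GPe-TA:
    source: GPe-TA
    target: GPe-TA
    K: 5
    weight: -0.11
    delay: 1.0
    beta_bi: -0.83
    beta_tri: -0.83
    beta: -0.83
    weight_normal: -0.11
  GPe-TA->GPe-TI:
    source: GPe-TA
    target: GPe-TI
    K: 5
    weight: -1.3
    delay: 1.0
    beta_bi: -0.83
    beta_tri: -0.83
    beta: -0.83
    weight_normal: -1.3
  GPe-TI->GPe-TA:
    source: GPe-TI
    target: GPe-TA
    K: 25
    weight: -0.35
    delay: 1.0
    beta_bi: -0.83
    beta_tri: -0.83
    beta: -0.83
    weight_normal: -0.35
  GPe-TI->GPe-TI:
    source: GPe-TI
    target: GPe-TI
    K: 25
    weight: -1.3
    delay: 1.0
    beta_bi: -0.83
    beta_tri: -0.83
    beta: -0.83
    weight_normal: -1.3
  GPe-TI->STN:
    source: GPe-TI
    target: STN
    K: 30
    weight: -0.3
    delay: 1.0
    beta_bi: -0.54
    beta_tri: -0.24
    beta: -0.54
    weight_normal: -0.3
stim_scale:
  D1-SPN: 1.0
  D2-SPN: 1.0
  STN: 1.0
  FSI: 1.0
rate_targets:
  D1-SPN:
  - 0.01
  - 2.0
  D2-SPN:
  - 0.01
  - 2.0
  FSI:
  - 10.0
  - 20.0
  STN:
  - 10.0
  - 13.0
  GPe-TA:
  - 10.699999999999999
  - 12.9
  GPe-TI:
  - 23.5
  - 24.899999999999999
  SNr:
  - 20.0
  - 35.0
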