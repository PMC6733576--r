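# Default model/protocol constants (published values; units in key names)
n_units: 15
bouton_len_um: 8.0
bouton_diam_um: 8.0
internode_len_um: 35.0
internode_diam_um: 0.8
wm_len_um: 150.0
wm_diam_um: 1.2
nseg_bouton: 3
nseg_internode: 7
nseg_wm: 11
cm_uF_per_cm2: 0.9
ri_ohm_cm: 120.0
e_na_mV: 55.0
e_k_mV: -97.0
e_hcn_mV: -23.3
myelin_factor: 10.0
wm_myelinated: true
g_nav_pS_per_um2: 2000.0
g_kv_pS_per_um2: 1000.0
g_leak_na_pS_per_um2: 0.0138
g_leak_k_pS_per_um2: 0.18
g_hcn_pS_per_um2: 0.3
g_hcn_axon_pS_per_um2: 0.03
# 0 mM cAMP HH gate parameters (A interpreted as per second by default)
hcn_A: 6.907
hcn_v_half_mV: -102.1
hcn_v_alpha_mV: 18.71
hcn_v_beta_mV: 21.73
hcn_rate_unit: per_s
# integration
dt_ms: 0.005
dt_passive_ms: 0.05
# tail-current analysis
tail_window_ms: [0.5, 2.5]
# dose-response
hill_fixed_h: null
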