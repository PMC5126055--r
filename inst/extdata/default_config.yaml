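rows: 50.0
cols: 50.0
dt: 0.1
trial_ms: 300.0
stn:
  a: 0.005
  b: 0.265
  c: -65.0
  d: 2.0
  v_peak: 30.0
  bias: 34.0
gpe:
  a: 0.1
  b: 0.2
  c: -65.0
  d: 2.0
  v_peak: 30.0
  bias: 4.2
gpi:
  a: 0.1
  b: 0.2
  c: -65.0
  d: 2.0
  v_peak: 30.0
  bias: 6.0
tau_exc: 5.0
tau_inh: 140.0
tau_str: 10.0
g_gpe_stn: 88.0
g_stn_gpe: 40.0
g_d2_gpe: 2.0
g_d1_gpi: 30.0
g_stn_gpi: 10.0
g_lat_stn: 15.75
g_lat_gpe: 7.875
da_coupling: 1.0
gpe_stn_floor: 0.1
da_healthy: 1.0
da_pd: 0.1
rate_min: 2.0
rate_max: 40.0
w_max: 2.0
w_floor: 0.1
outcome_scale: 0.01
race_drive: 0.0475
race_gain: 0.0005
race_leak: 0.01
race_noise: 0.05
race_threshold: 1.0
tau_rate: 2.0
race_onset: 150.0
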