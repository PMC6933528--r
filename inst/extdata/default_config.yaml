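# Reference configuration of the three-population sleep-wake network.
# Flat key: value; any key may be overridden from load_config() or the CLI.
W_max: 5
N_max: 5
R_max: 5
alpha_W: 0.25
alpha_N: 0.25
alpha_R: 0.25
beta_W: -1.1
beta_R: -1.2
k_N: -2.5
tau_W: 30
tau_N: 30
tau_R: 30
H_max: 1
theta_W: 2
tau_hw: 10800
tau_hs: 5400
tau_C_W: 4
tau_C_N: 2
tau_C_R: 5
gamma_C_W: 4
gamma_C_N: 2
gamma_C_R: 5
g_RRe: 1.6
g_RWe: 1.0
g_WNi: -2.0
g_WRi: -4.0
g_NRi: -1.3
g_NWi: -1.68
noise_mean: 0.01
noise_sd: 0.005
dt: 0.001
duration: 86400
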