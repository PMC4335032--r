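# Canonical parameter set of the working-memory attractor network.
# Units: time constants and steps in seconds, potentials/efficacies in mV,
# rates in Hz. J_minus is derived, never configured. mu_ext_E / mu_ext_I are
# absent on purpose: they are produced by mean-field calibration.
p: 6
f: 0.05
N_E: 1600
N_I: 400
tau_E: 0.02
tau_I: 0.01
theta: 20.0
V_R: 10.0
tau_arp: 0.0025
sigma: 0.75
sigma_BG: 1.0
sigma_S: 2.0
tau_AMPA: 0.005
tau_NMDA: 0.05
tau_GABA: 0.005
X_E: 0.7
X_I: 0.002
J_EE: 0.025
J_IE: 0.0625
J_EI: 0.075
J_II: 0.1
J_plus: 0.156
nu_E_sp: 0.75
nu_I_sp: 5.0
dt_spiking: 1.0e-4
dt_rate: 1.0e-3
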