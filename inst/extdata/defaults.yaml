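# Default parameter profile for the two-state condensate swimming model.
# Dimensionless model units. dt and tau_star follow the reference run
# (dt = 0.01, tau_star = 800 * dt, m_L0 = 100, m_D0 = 0); the mass-transfer
# and momentum constants are the package's one-time calibration reproducing
# the three qualitative swimming regimes of the default frequency sweep
# (see the methods vignette, "Default calibration").
A_max: 0.3
lambda_max: 0.7
B: 0.3
kappa: 0.05
tau_star: 8.0
dt: 0.01
v_eject: 0.5
v_reverse: 2.0
gamma: 0.2
beta: 0.02
exchange_enabled: true
m_L0: 100.0
# default three-frequency sweep (low / intermediate / high, f = 1/(2T))
frequencies: [0.0125, 0.125, 0.625]
horizon: 300.0
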