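experiment: gait_optimization
physical: {L: 20, N: 40, r: 1.0, E: 7.0e5, E_units: Pa}
drag: {variant: taylor}
activation:
  kind: gait_family
  f: 2
  gait: {K1: 1.0, K2: 1.5, K3: 2.0, K4: 2.4, tau: 1.0, T: 0.5, L: 20}
integration: {method: ode45}
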