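experiment: validation
physical: {L: 20, N: 40, r: 1.0, E: 7.0e5, E_units: Pa}
drag: {variant: taylor}
activation: {kind: traveling_wave, B: 2.5, f: 2, wavelength: 20}
integration: {t_end: 2.5, max_step: 1.0e-3, method: ode45}
sweep: {parameter: B, values: [2.5, 3.5]}
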