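experiment: frequency_sweep
physical: {L: 20, N: 40, r: 1.0, E: 7.0e5, E_units: Pa}
drag: {variant: taylor}
activation: {kind: traveling_wave, B: 2.5, wavelength: 20}
sweep: {parameter: f, values: [2, 4, 8, 16, 32, 64]}
integration: {method: ode45}
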