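experiment: stiffness_sweep
physical: {L: 20, N: 40, r: 1.0, E_units: Pa}
drag: {variant: taylor}
activation: {kind: traveling_wave, B: 2.5, f: 2, wavelength: 20}
sweep: {parameter: E, values: [3.16e3, 1.26e4, 5.01e4, 2.0e5, 7.9e5, 3.16e6]}
integration: {method: ode45}
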