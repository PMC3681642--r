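experiment: modes
physical: {L: 1, N: 40, r: 0.05, E: 7.0e5, E_units: Pa}
drag: {variant: lighthill, wavelength: 1}
activation: {kind: traveling_wave, B: 0.125, f: 20, wavelength: 1}
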