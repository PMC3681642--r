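experiment: passive_forced
physical: {L: 20, N: 40, r: 1.0, E: 7.0e5, E_units: Pa}
drag: {variant: linearized, CN: 10, CT: 5}
forcing: {F0: 1500, T0: 5.0e4, omega_f: 12.566, phi_grid_points: 16}
integration: {t_end: 18}
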