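experiment: passive_flow
physical: {L: 20, N: 40, r: 1.0, E: 7.0e5, E_units: Pa}
drag: {variant: linearized, CN: 10, CT: 5}
flow: {Vf: 10, lambda_f: 10, f_f: 2, direction: 1}
integration: {t_end: 20, method: ode45}
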