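# Glucagon: same PRC shape as OXM scaled to a -3 h maximal delay at 180
# degrees, effective only at high concentrations (EC50 80 nM, steep).
peptide_name: GCG
prc_coefficients: [-0.9375, 0.0, 1.5, 0.0, -0.5625]
ec50: 80.0
hill_n: 2.0
amplitude_damping_factor: 0.9
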