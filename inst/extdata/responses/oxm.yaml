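# Oxyntomodulin: maximal delay -8 h at 180 degrees, near-null at 0/270,
# potent at low doses (EC50 5 nM).
peptide_name: OXM
prc_coefficients: [-2.5, 0.0, 4.0, 0.0, -1.5]
ec50: 5.0
hill_n: 1.0
amplitude_damping_factor: 0.8
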