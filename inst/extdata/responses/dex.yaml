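# Dexamethasone: biphasic PRC, delays in 0-90 degrees, advances in 100-180,
# no marked effect around 270; used at 100 uM (1e5 nM), well above EC50.
peptide_name: DEX
prc_coefficients: [0.0, 0.0, 0.0, -3.0, 0.0]
ec50: 5000.0
hill_n: 1.0
amplitude_damping_factor: 1.0
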