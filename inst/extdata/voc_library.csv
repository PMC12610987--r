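name,formula,neutral_mass
ammonia,NH3,17.026549
methanol,CH4O,32.026215
carbon dioxide (formic acid fragment),CO2,43.989829
acetaldehyde,C2H4O,44.026215
formic acid,CH2O2,46.005479
ethanol,C2H6O,46.041865
1_2-butadiene,C4H6,54.046950
acetone,C3H6O,58.041865
acetic acid,C2H4O2,60.021129
dimethyl sulfide,C2H6S,62.019021
isoprene,C5H8,68.062600
propylene glycol,C3H8O2,76.052429
benzene,C6H6,78.046950
toluene,C7H8,92.062600
phenol,C6H6O,94.041865
indole,C8H7N,117.057849
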