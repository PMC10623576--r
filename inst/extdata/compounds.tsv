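name	monoisotopic_mass	henry_constant	gas_phase_basicity
acetone	58.041865	0.67	782.1
d6-acetone	64.079527	0.67	782.1
d3-acoh	63.039960	99.15	752.8
pyridine	79.042199	2.73	898.1
ammonia	17.026549	1.49	819.0
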