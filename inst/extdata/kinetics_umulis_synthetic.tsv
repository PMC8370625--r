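# Hepatic Michaelis-Menten parameter set in the style of the external
# Umulis-type ethanol/acetaldehyde PK parameterisation. SYNTHETIC STAND-IN:
# values are representative literature-scale constants, shipped so that the
# coupled model is runnable out of the box; users with the original external
# parameter file may drop in their own values (same schema).
# Units: Vmax mM/min (per litre of host organ), Km mM.
parameter	value
vmax_adh	2.2
km_adh	0.4
vmax_aldh2	2.7
km_aldh2	0.0012
vmax_aldh2_colon	0.5
km_aldh2_colon	0.0012
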