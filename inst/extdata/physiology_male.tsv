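# Reference-man physiology table (male), version 1.
# Convention: ref_volume_L are organ volumes for a 73 kg, 20% body-fat reference
# male (lean mass 58.4 kg). Non-adipose organ volumes scale with lean body mass;
# adipose volume is weight * body_fat / 0.916 (adipose density kg/L). Flow
# fractions are fractions of cardiac output and sum to exactly 1 over systemic
# organs (lung carries the full cardiac output; lumina carry no blood flow).
# water/nlipid/plipid are tissue composition fractions (mass/volume) used for
# tissue:plasma partitioning; plasma_reference is the reference phase.
organ	ref_volume_L	flow_frac	water	nlipid	plipid	is_lumen	portal
lung	0.50	1.000	0.811	0.0030	0.0090	0	0
liver	1.80	0.075	0.745	0.0350	0.0250	0	0
stomach	0.15	0.012	0.718	0.0487	0.0163	0	1
small_intestine	0.65	0.115	0.718	0.0487	0.0163	0	1
large_intestine	0.37	0.045	0.718	0.0487	0.0163	0	1
pancreas	0.14	0.012	0.664	0.0410	0.0093	0	1
spleen	0.15	0.026	0.788	0.0200	0.0198	0	1
kidney	0.31	0.215	0.783	0.0210	0.0160	0	0
skin	3.30	0.060	0.718	0.0320	0.0110	0	0
muscle	29.00	0.200	0.760	0.0220	0.0072	0	0
adipose	15.94	0.060	0.180	0.7900	0.0020	0	0
brain	1.45	0.135	0.770	0.0510	0.0565	0	0
heart	0.33	0.045	0.779	0.0140	0.0110	0	0
blood	5.60	0.000	0.945	0.0035	0.00225	0	0
stomach_lumen	0.25	0.000	1.000	0.0000	0.0000	1	0
si_lumen	0.50	0.000	1.000	0.0000	0.0000	1	0
li_lumen	0.50	0.000	1.000	0.0000	0.0000	1	0
plasma_reference	0.00	0.000	0.945	0.0035	0.00225	0	0
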