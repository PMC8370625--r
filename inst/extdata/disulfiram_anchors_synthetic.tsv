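# Blood disulfiram concentration (uM) -> relative ALDH2 activity anchors.
# SYNTHETIC STAND-IN for the in-vitro inhibition anchor table (sheep-liver
# enzyme preparations); monotone nonincreasing with activity(0) = 1. The
# package fits a single-parameter exponential inhibition curve through these
# anchors; the anchors, not the functional form, are authoritative.
disulfiram_uM	relative_activity
0	1.00
5	0.55
10	0.32
20	0.12
40	0.04
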