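# Drink-strength -> gut absorption/transport rate anchors. SYNTHETIC STAND-IN
# for the fitted beverage-arm anchors (beer 5.1, wine 12.5, spirits 20 %w/v):
# encodes the calibrated qualitative structure (absorption and gastric transit
# accelerate with drink strength) with literature-scale first-order rates.
# Re-fitting against observed blood-ethanol curves regenerates this table.
# Units: 1/min.
strength_wv	k_stom	k_si	k_stomsi
5.1	0.020	0.080	0.035
12.5	0.035	0.120	0.060
20	0.055	0.160	0.090
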