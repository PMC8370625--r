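# Physicochemical records for the two tracked metabolites.
# lipophilicity is log10 octanol:water partition; fraction_unbound is the
# unbound fraction in plasma.
name	molecular_weight	lipophilicity	fraction_unbound
ethanol	46.07	-0.31	0.99
acetaldehyde	44.05	-0.34	0.99
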