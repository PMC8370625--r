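# ALDH2 isoform activity table (homozygous genotypes), in-vitro activities
# relative to wild type.
isoform	mutation	allelic_frequency_pct	major_ethnicity	activity_pct
ALDH2.1	WT	NA	NA	100
ALDH2.2	E504K	26.6	East_Asia	1.5
ALDH2.3	I41V	0.6	African	60
ALDH2.4	P92T	2.5	Latino	32.5
ALDH2.5	T244M	0.4	South_Asian	36
ALDH2.6	V304M	2.7	Latino	12.5
ALDH2.7	R338W	1.2	Finnish	23
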