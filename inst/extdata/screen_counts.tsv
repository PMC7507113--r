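label	numerator	denominator	decimals	printed_pct
patescibacteria_of_all_sags	770	4829	0	16
dpann_of_all_sags	113	4829	0	2
marker_cosort_patescibacteria	5	492	0	1
marker_cosort_dpann	1	81	1	1.2
marker_cosort_other	5	1686	1	0.3
ssu_cosort_patescibacteria	4	262	1	1.5
ssu_cosort_other	4	758	2	0.53
o2red_patescibacteria	3	492	1	0.6
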