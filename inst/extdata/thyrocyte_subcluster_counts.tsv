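subcluster	C1_count	C1_pct	C3_count	C3_pct	total_count	total_pct
Thyrocytes0	7790	61.17	6322	61.04	14112	61.11
Thyrocytes1	1360	10.68	1988	19.19	3348	14.5
Thyrocytes2	1240	9.74	1165	11.25	2405	10.41
Thyrocytes3	939	7.37	472	4.56	1411	6.11
Thyrocytes4	750	5.89	219	2.11	969	4.2
Thyrocytes5	414	3.25	186	1.8	600	2.6
Thyrocytes6	243	1.91	5	0.05	248	1.07
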