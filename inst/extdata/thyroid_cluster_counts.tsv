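cluster	C1_count	C1_pct	C2_count	C2_pct	C3_count	C3_pct	total_count	total_pct
Thyrocyte0	9361	68.1	8150	65.93	6952	63.96	24463	66.16
Thyrocyte1	3375	24.55	2759	22.32	3405	31.33	9539	25.8
Endothelial_L	366	2.66	525	4.25	196	1.8	1087	2.94
Endothelial_V	209	1.52	57	0.46	79	0.73	345	0.93
Fibroblasts	269	1.96	154	1.25	134	1.23	557	1.51
Mixed_Tcells	98	0.71	477	3.86	62	0.57	637	1.72
Myeloid	54	0.39	75	0.61	41	0.38	170	0.46
C.Cells	13	0.09	2	0.02	0	0	15	0.04
Mixed_Bcells	1	0.01	163	1.32	0	0	164	0.44
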