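MITO_ETC_PROGRAM	toy set	G0015	G0016	G0017	G0018	G0019	G0020	G0021	G0022	G0023	G0024	G0025	G0026	G0027	G0028	G0029	G0030	G0031	G0032	G0033	G0034	G0035	G0036	G0037	G0038	G0039
RIBOSOME_TRANSLATION_PROGRAM	toy set	G0040	G0041	G0042	G0043	G0044	G0045	G0046	G0047	G0048	G0049	G0050	G0051	G0052	G0053	G0054	G0055	G0056	G0057	G0058	G0059	G0060	G0061	G0062	G0063	G0064
NUCLEAR_ETC_PROGRAM	toy set	G0065	G0066	G0067	G0068	G0069	G0070	G0071	G0072	G0073	G0074	G0075	G0076	G0077	G0078	G0079	G0080	G0081	G0082	G0083	G0084	G0085	G0086	G0087	G0088	G0089
CHRX_LOCUS_PROGRAM	toy set	G0090	G0091	G0092	G0093	G0094	G0095	G0096	G0097	G0098	G0099	G0100	G0101	G0102	G0103	G0104	G0105	G0106	G0107	G0108	G0109	G0110	G0111	G0112	G0113	G0114
CYTOSKELETON_PROGRAM	toy set	G0115	G0116	G0117	G0118	G0119	G0120	G0121	G0122	G0123	G0124	G0125	G0126	G0127	G0128	G0129	G0130	G0131	G0132	G0133	G0134	G0135	G0136	G0137	G0138	G0139
NEURONAL_PROGRAM	toy set	G0140	G0141	G0142	G0143	G0144	G0145	G0146	G0147	G0148	G0149	G0150	G0151	G0152	G0153	G0154	G0155	G0156	G0157	G0158	G0159	G0160	G0161	G0162	G0163	G0164
ENDOTHELIAL_L_SIGNATURE	toy set	G0165	G0166	G0167	G0168	G0169	G0170	G0171	G0172	G0173	G0174
ENDOTHELIAL_V_SIGNATURE	toy set	G0175	G0176	G0177	G0178	G0179	G0180	G0181	G0182	G0183	G0184
FIBROBLAST_SIGNATURE	toy set	G0185	G0186	G0187	G0188	G0189	G0190	G0191	G0192	G0193	G0194
TCELL_SIGNATURE	toy set	G0195	G0196	G0197	G0198	G0199	G0200	G0201	G0202	G0203	G0204
MYELOID_SIGNATURE	toy set	G0205	G0206	G0207	G0208	G0209	G0210	G0211	G0212	G0213	G0214
BCELL_SIGNATURE	toy set	G0215	G0216	G0217	G0218	G0219	G0220	G0221	G0222	G0223	G0224
RANDOM_01	toy set	G0513	G0524	G0246	G0470	G0586	G0450	G0352	G0582	G0493	G0244	G0292	G0489	G0434	G0312	G0382
RANDOM_02	toy set	G0310	G0564	G0356	G0302	G0577	G0231	G0434	G0423	G0318	G0453	G0456	G0567	G0282	G0534	G0270
RANDOM_03	toy set	G0268	G0410	G0545	G0366	G0284	G0415	G0390	G0455	G0431	G0384	G0565	G0295	G0347	G0509	G0525
RANDOM_04	toy set	G0492	G0425	G0579	G0328	G0532	G0467	G0518	G0539	G0264	G0327	G0530	G0292	G0495	G0509	G0319
RANDOM_05	toy set	G0586	G0412	G0315	G0282	G0330	G0405	G0536	G0508	G0512	G0239	G0324	G0497	G0323	G0263	G0409
RANDOM_06	toy set	G0403	G0531	G0472	G0325	G0292	G0254	G0227	G0592	G0541	G0317	G0235	G0496	G0410	G0267	G0535
RANDOM_07	toy set	G0424	G0467	G0371	G0274	G0358	G0431	G0582	G0426	G0349	G0530	G0305	G0433	G0326	G0541	G0416
RANDOM_08	toy set	G0498	G0576	G0356	G0260	G0480	G0497	G0338	G0327	G0379	G0314	G0536	G0271	G0517	G0570	G0335
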