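index	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
hydropathy_kyte_doolittle	1.8	-4.5	-3.5	-3.5	2.5	-3.5	-3.5	-0.4	-3.2	4.5	3.8	-3.9	1.9	2.8	-1.6	-0.8	-0.7	-0.9	-1.3	4.2
hydrophilicity_hopp_woods	-0.5	3.0	0.2	3.0	-1.0	0.2	3.0	0.0	-0.5	-1.8	-1.8	3.0	-1.3	-2.5	0.0	0.3	-0.4	-3.4	-2.3	-1.5
residue_volume_zamyatnin	88.6	173.4	114.1	111.1	108.5	143.8	138.4	60.1	153.2	166.7	166.7	168.6	162.9	189.9	112.7	89.0	116.1	227.8	193.6	140.0
polarity_grantham	8.1	10.5	11.6	13.0	5.5	10.5	12.3	9.0	10.4	5.2	4.9	11.3	5.7	5.2	8.0	9.2	8.6	5.4	6.2	5.9
net_charge	0	1	0	-1	0	0	-1	0	0	0	0	1	0	0	0	0	0	0	0	0
eiip_veljkovic	0.0373	0.0959	0.0036	0.1263	0.0829	0.0761	0.0058	0.0050	0.0242	0.0000	0.0000	0.0371	0.0823	0.0946	0.0198	0.0829	0.0941	0.0548	0.0516	0.0057
isoelectric_point	6.00	10.76	5.41	2.77	5.05	5.65	3.22	5.97	7.59	6.02	5.98	9.74	5.74	5.48	6.30	5.68	5.66	5.89	5.66	5.96
residue_mass	71.08	156.19	114.10	115.09	103.14	128.13	129.12	57.05	137.14	113.16	113.16	128.17	131.19	147.18	97.12	87.08	101.10	186.21	163.18	99.13
helix_propensity_chou_fasman	1.42	0.98	0.67	1.01	0.70	1.11	1.51	0.57	1.00	1.08	1.21	1.16	1.45	1.13	0.57	0.77	0.83	1.08	0.69	1.06
sheet_propensity_chou_fasman	0.83	0.93	0.89	0.54	1.19	1.10	0.37	0.75	0.87	1.60	1.30	0.74	1.05	1.38	0.55	0.75	1.19	1.37	1.47	1.70
turn_propensity_chou_fasman	0.66	0.95	1.56	1.46	1.19	0.98	0.74	1.56	0.95	0.47	0.59	1.01	0.60	0.60	1.52	1.43	0.96	0.96	1.14	0.50
hydrophobicity_eisenberg	0.62	-2.53	-0.78	-0.90	0.29	-0.85	-0.74	0.48	-0.40	1.38	1.06	-1.50	0.64	1.19	0.12	-0.18	-0.05	0.81	0.26	1.08
flexibility_bhaskaran	0.357	0.529	0.463	0.511	0.346	0.493	0.497	0.544	0.323	0.462	0.365	0.466	0.295	0.314	0.509	0.507	0.444	0.305	0.420	0.386
polarizability_charton	0.046	0.291	0.134	0.105	0.128	0.180	0.151	0.000	0.230	0.186	0.186	0.219	0.221	0.290	0.131	0.062	0.108	0.409	0.298	0.140
accessible_surface_area	115	225	160	150	135	180	190	75	195	175	170	200	185	210	145	115	140	255	230	155
transfer_energy_janin	0.3	-1.4	-0.5	-0.6	0.9	-0.7	-0.7	0.3	-0.1	0.7	0.5	-1.8	0.4	0.5	-0.3	-0.1	-0.2	0.3	-0.4	0.6
bulkiness_zimmerman	11.50	14.28	12.82	11.68	13.46	14.45	13.57	3.40	13.69	21.40	21.40	15.71	16.25	19.80	17.43	9.47	15.77	21.67	18.03	21.57
refractivity_jones	4.34	26.66	13.28	12.00	35.77	17.56	17.26	0.00	21.81	19.06	18.78	21.29	21.64	29.40	10.93	6.35	11.01	42.53	31.53	13.92
relative_mutability_dayhoff	100	65	134	106	20	93	102	49	66	96	40	56	94	41	56	120	97	18	41	74
octanol_transfer_fauchere	0.31	-1.01	-0.60	-0.77	1.54	-0.22	-0.64	0.00	0.13	1.80	1.70	-0.99	1.23	1.79	0.72	-0.04	0.26	2.25	0.96	1.22
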