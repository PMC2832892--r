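# 117-entry intermediate-size ncRNA catalog: northern-blot calls and cross-species conservation scores
name	clone_count	length_nt	probe_id	det_chicken	det_mouse	det_human	cons_chicken	cons_mouse	cons_human	consistent	group_label
7SK	9	332	MT721	yes	yes	yes	0.98	1	1	Y	1
RNaseP_nuc	1	340	MP733	yes	yes	yes	0.12	0.36	1	Y	1
SNORA61	1	131	MP2422	yes	yes	yes	0.42	0.36	1	Y	1
SNORA66	4	131	MP405	yes	yes	yes	0.69	0.83	1	Y	1
SNORA81	26	179	MP284	yes	yes	yes	0.42	0.99	1	Y	1
SNORD94	5	135	MP141	yes	yes	yes	0.64	1	1	Y	1
7SLa	1	299	MP477	yes	yes	yes	0.97	1	1	Y	1
7SLb	2	300	MP477	yes	yes	yes	0.97	1	1	Y	1
U1-1	14	164	MT369	yes	yes	yes	1	1	1	Y	1
U1-2	17	166	MT369	yes	yes	yes	1	1	1	Y	1
U1-3	23	166	MT369	yes	yes	yes	1	1	1	Y	1
U12	12	150	MT305	yes	yes	yes	0.87	1	1	Y	1
U2-1	5	184	MP76	no	yes	yes	0.99	1	1	Y	1
U2-2	21	188	MP76	no	yes	yes	0.99	1	1	Y	1
U3a	12	148	MT42	yes	yes	yes	0.70	0.81	1	Y	1
U3b	9	217	MT42	yes	yes	yes	0.72	0.8	1	Y	1
U3c	7	218	MT42	yes	yes	yes	0.71	0.82	1	Y	1
U3d	10	218	MT42	yes	yes	yes	0.70	0.80	1	Y	1
U3e	8	219	MT42	yes	yes	yes	0.73	0.82	1	Y	1
U3f	6	221	MT42	yes	yes	yes	0.70	0.81	1	Y	1
U3g	6	216	MT42	yes	yes	yes	0.71	0.83	1	Y	1
U3h	9	216	MT42	yes	yes	yes	0.72	0.81	1	Y	1
U3i	7	216	MT42	yes	yes	yes	0.70	0.80	1	Y	1
U3j	2	216	MT42	yes	yes	yes	0.73	0.82	1	Y	1
U3k	20	217	MT42	yes	yes	yes	0.71	0.81	1	Y	1
U3l	5	217	MT42	yes	yes	yes	0.73	0.80	1	Y	1
U3m	7	217	MT42	yes	yes	yes	0.72	0.84	1	Y	1
U3n	6	217	MT42	yes	yes	yes	0.70	0.83	1	Y	1
U4	10	146	MT365	yes	yes	yes	0.99	0.99	1	Y	1
U5-1	1	97	MP235	yes	yes	yes	0.70	0.99	0.88	Y	1
U5-2	6	118	MP235	yes	yes	yes	0.75	0.99	0.88	Y	1
U5-3	9	121	MP235	yes	yes	yes	0.74	0.99	0.88	Y	1
U5-4	8	121	MP235	yes	yes	yes	0.73	0.99	0.88	Y	1
U5-5	6	124	MP235	yes	yes	yes	0.78	0.99	0.88	Y	1
U6-1	35	89	MT44	yes	yes	yes	1	1	1	Y	1
U6-2	48	104	MT44	yes	yes	yes	1	1	1	Y	1
U6atac	43	127	MT65	yes	yes	yes	0.96	0.96	1	Y	1
unclassified 2	1	51	MT4702	yes	yes	yes	0.94	0.94	0.94	Y	1
Y5	30	102	MP281	yes	yes	yes	0.62	1	1	Y	1
Y6	81	112	MP91	yes	yes	yes	1	1	1	Y	1
RNase_MRP	1	146	MP690	no	yes	yes	0.15	0.39	1	Y	2
SCARNA11	2	144	MP66	no	yes	yes	0.16	0.85	1	Y	2
SCARNA15	2	127	MP77	no	yes	yes	0.22	0.99	1	Y	2
SCARNA25	3	142	MP407	no	yes	yes	0.17	1	0.98	Y	2
SCARNA4	3	128	MP400	no	yes	yes	0.23	0.98	1	Y	2
SNORA11	1	115	MP4400	no	yes	yes	0.20	0.51	1	Y	2
SNORA13	1	135	MP243	no	yes	yes	0.19	0.99	1	Y	2
SNORA14	2	132	MP227	no	yes	yes	0.20	0.99	1	Y	2
SNORA15	2	138	MP236	no	yes	yes	0.20	0.46	0.98	Y	2
SNORA17	2	134	MP695	no	yes	yes	0.16	0.87	1	Y	2
SNORA18	5	133	MP17	no	yes	yes	0.23	0.98	1	Y	2
SNORA2	1	137	MP4598	no	yes	yes	0.17	0.99	1	Y	2
SNORA23	2	189	MP268	no	yes	yes	0.23	0.94	1	Y	2
SNORA24	2	130	MP252	no	yes	yes	0.41	1	1	Y	2
SNORA28	3	129	MP306	no	yes	yes	0.31	0.92	1	Y	2
SNORA36a	3	132	MP207	no	yes	yes	0.42	0.98	1	Y	2
SNORA36b	2	132	MP207	no	yes	yes	0.45	0.52	1	Y	2
SNORA4	6	140	MP374	no	yes	yes	0.17	0.44	1	Y	2
SNORA41	1	131	MP4579	no	yes	yes	0.20	0.56	0.98	Y	2
SNORA42	1	139	MP4011	no	yes	yes	0.22	0.86	1	Y	2
SNORA49	2	138	MP427	no	yes	yes	0.20	0.88	1	Y	2
SNORA5	3	135	MP4812	no	yes	yes	0.45	0.84	1	Y	2
SNORA53	2	248	MP750	no	yes	yes	0.29	1	1	Y	2
SNORA54	2	124	MP319	no	yes	yes	0.24	1	1	Y	2
SNORA58	4	137	MP4121	no	yes	yes	0.21	0.52	1	Y	2
SNORA62	8	150	MP86	no	yes	yes	0.17	1	0.99	Y	2
SNORA63	13	135	MP32	no	yes	yes	0.19	0.99	1	Y	2
SNORA7	1	140	MP4777	no	yes	yes	0.20	0.96	1	Y	2
SNORA70	1	135	MP4769	no	yes	yes	0.23	0.70	1	Y	2
SNORA71	3	138	MP241	no	yes	yes	0.19	0.83	1	Y	2
SNORA72	5	132	MP356	no	yes	yes	0.19	0.96	1	Y	2
SNORA74a	2	134	MP2697	no	yes	yes	0.12	1	1	Y	2
SNORA74b	2	203	MP4370	no	yes	yes	0.12	1	1	Y	2
SNORD13	23	104	MT370	no	yes	yes	0.21	0.74	1	Y	2
SNORD15	2	142	MP4	no	yes	yes	0.23	1	1	Y	2
SNORD17a	2	250	MP20	no	yes	yes	0.12	1	0.99	Y	2
SNORD17b	6	257	MP20	no	yes	yes	0.12	1	0.99	Y	2
SNORD22	1	126	MP4712	no	yes	yes	0.21	1	1	Y	2
SNORD46	3	101	MP329	no	yes	yes	0.26	0.96	0.96	Y	2
SNORD67	1	104	MP4243	no	yes	yes	0.45	0.98	0.98	Y	2
snoU6-53	3	110	MP277	no	yes	yes	0.24	0.98	1	Y	2
U11	4	136	MP1393	no	yes	yes	0.29	1	1	Y	2
U4atac	35	131	MT4	no	yes	yes	0.19	0.98	1	Y	2
unclassified 6	1	137	MP2665	no	yes	yes	0.18	0.26	0.99	Y	2
unclassified 7	2	143	MP232	no	yes	yes	0.17	0.99	1	Y	2
Vault RNA	2	89	MP331	no	yes	yes	0.21	0.25	0.53	Y	2
SNORD116	3	90	MT4173	no	no	yes	0.28	0.77	1	Y	2
SNORA31	7	128	MP312	no	yes	yes	0.66	1	1	N	2
SNORA73	1	119	MP4480	no	yes	yes	0.97	0.97	0.96	N	2
SNORA8	1	140	MP4084	no	yes	yes	0.69	0.99	1	N	2
SNORD16	1	94	MT2039	no	yes	yes	0.85	1	1	N	2
SNORA25	2	133	MP3076	no	no	yes	0.18	0.56	0.99	Y	3
SNORA64	1	132	MP4716	no	no	yes	0.18	0.21	1	Y	3
SNORA68	1	133	MP2580	no	no	yes	0.18	0.32	1	Y	3
SNORD24	1	71	MT325	no	no	yes	0.32	0.32	1	Y	3
U8	8	137	MT180	no	no	yes	0.17	0.46	1	Y	3
unclassified 8	1	153	MP472	no	no	yes	0.16	0.18	1	Y	3
Y1	1	77	MP727	no	no	yes	0.27	0.51	0.92	Y	3
Y2	4	90	MP727	no	no	yes	0.26	0.49	0.92	Y	3
Y3	34	90	MP727	no	no	yes	0.25	0.53	0.92	Y	3
Y4	25	96	MT274	no	no	yes	0.27	0.27	1	Y	3
SNORA19	4	132	MP4158	no	no	yes	0.40	0.99	1	N	3
SNORA27	3	128	MP464	no	no	yes	0.22	0.98	1	N	3
SNORA40	1	130	MP4587	no	no	yes	0.22	0.77	1	N	3
SNORA43	1	134	MP2188	no	no	yes	0.16	0.76	1	N	3
SNORA76	1	135	MP1373	no	no	yes	0.18	0.93	0.99	N	3
snosnR60_Z15	1	68	MT2333	no	no	yes	1	1	1	N	3
SNORA20	2	133	MP4330	no	no	no	0.18	0.18	1	N	4
SNORD26	1	139	MP2208	no	no	no	0.20	0.97	0.98	N	4
SNORD27	2	69	MP299	no	no	no	0.36	0.72	1	N	4
SNORD87	1	77	MP4391	no	no	no	0.31	0.48	1	N	4
unclassified 1	7	51	MT3898	no	no	no	0.63	1	1	N	4
unclassified 3	2	52	MT3338	no	no	no	**	**	**	**	4
unclassified 4	1	67	MP2207	no	no	no	0.32	0.35	0.65	N	4
unclassified 5	2	75	MP2233	no	no	no	0.33	0.55	0.99	N	4
SNORD45	1	77	MP2242	no	yes	no	0.34	1	1	N	5
SNORA50	3	136	MP2895	yes	no	yes	0.98	1	1	N	6
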