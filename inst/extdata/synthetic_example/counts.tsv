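taxon	trt01_r1_t00	trt01_r2_t00	trt01_r3_t00	trt01_r1_t01	trt01_r2_t01	trt01_r3_t01	trt01_r1_t02	trt01_r2_t02	trt01_r3_t02	trt01_r1_t03	trt01_r2_t03	trt01_r3_t03	trt01_r1_t04	trt01_r2_t04	trt01_r3_t04	trt01_r1_t05	trt01_r2_t05	trt01_r3_t05	trt02_r1_t00	trt02_r2_t00	trt02_r3_t00	trt02_r1_t01	trt02_r2_t01	trt02_r3_t01	trt02_r1_t02	trt02_r2_t02	trt02_r3_t02	trt02_r1_t03	trt02_r2_t03	trt02_r3_t03	trt02_r1_t04	trt02_r2_t04	trt02_r3_t04	trt02_r1_t05	trt02_r2_t05	trt02_r3_t05
otu0001	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	22	25	17	15	27	23	19	13	11	25	19	24	25	19	23	13	23	21
otu0002	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	15	12	10	11	9	14	18	17	15	6	11	19	19	13	10	13	9	16
otu0003	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	36	34	35	37	40	36	37	34	39	32	30	39	41	38	29	46	32	40
otu0004	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
otu0005	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0006	15	9	22	14	20	13	18	17	21	13	14	17	24	15	11	24	25	16	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0007	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	253	270	242	220	248	228	223	238	227	238	241	244	219	233	237	229	213	220
otu0008	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0
otu0009	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	1	0	1	0	0	0	0	0	0	0	0	0
otu0010	9	12	8	7	10	5	8	10	10	11	6	4	6	8	7	8	10	13	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0011	61	58	78	64	54	61	60	65	63	46	45	57	59	59	56	69	69	50	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0012	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0013	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0014	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0015	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	191	222	223	232	222	210	239	216	230	198	229	187	212	222	203	219	223	215
otu0016	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	12	9	13	19	19	20	18	18	15	18	15	15	18	15	13	19	11	14
otu0017	375	376	353	375	359	379	343	382	370	359	386	373	374	378	364	351	368	373	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0018	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0019	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	5	5	2	6	2	2	3	3	3	2	1	2	3	4	2
otu0020	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0	0
otu0021	47	35	33	37	43	25	47	37	46	54	48	44	43	47	37	46	32	50	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0022	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	2	1	3	1	1	3	4	1	3	2	1	3	2	2	4	4	2
otu0023	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	2	2	3	3	1	0	1	2	0	1	1	0	4
otu0024	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	17	15	13	19	18	18	16	23	16	24	15	17	23	13	15	15	13	15
otu0025	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0026	26	29	42	27	31	33	28	31	27	32	38	24	25	33	44	35	35	25	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0027	1	1	1	1	2	0	0	0	0	2	0	2	4	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu0028	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	1	5	5	5	2	3	3	1	6	3	8	6	5	2	1	3	6
otu0029	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	446	407	437	433	406	443	415	429	438	446	431	442	430	439	463	437	465	444
otu0030	464	480	463	474	481	484	496	458	463	483	463	479	465	459	481	467	461	472	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
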