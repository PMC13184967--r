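sample	treatment	replicate	timepoint
trt01_r1_t00	trt01	r1	0
trt01_r2_t00	trt01	r2	0
trt01_r3_t00	trt01	r3	0
trt01_r1_t01	trt01	r1	1
trt01_r2_t01	trt01	r2	1
trt01_r3_t01	trt01	r3	1
trt01_r1_t02	trt01	r1	2
trt01_r2_t02	trt01	r2	2
trt01_r3_t02	trt01	r3	2
trt01_r1_t03	trt01	r1	3
trt01_r2_t03	trt01	r2	3
trt01_r3_t03	trt01	r3	3
trt01_r1_t04	trt01	r1	4
trt01_r2_t04	trt01	r2	4
trt01_r3_t04	trt01	r3	4
trt01_r1_t05	trt01	r1	5
trt01_r2_t05	trt01	r2	5
trt01_r3_t05	trt01	r3	5
trt02_r1_t00	trt02	r1	0
trt02_r2_t00	trt02	r2	0
trt02_r3_t00	trt02	r3	0
trt02_r1_t01	trt02	r1	1
trt02_r2_t01	trt02	r2	1
trt02_r3_t01	trt02	r3	1
trt02_r1_t02	trt02	r1	2
trt02_r2_t02	trt02	r2	2
trt02_r3_t02	trt02	r3	2
trt02_r1_t03	trt02	r1	3
trt02_r2_t03	trt02	r2	3
trt02_r3_t03	trt02	r3	3
trt02_r1_t04	trt02	r1	4
trt02_r2_t04	trt02	r2	4
trt02_r3_t04	trt02	r3	4
trt02_r1_t05	trt02	r1	5
trt02_r2_t05	trt02	r2	5
trt02_r3_t05	trt02	r3	5
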