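rank	population	mean	sem
1	YX	0.8	0.0387
2	HX	0.6667	0.0771
3	GZL	0.578	0.0588
3	SY	0.578	0.089
5	GY	0.511	0.022
5	YZ	0.511	0.097
7	TC	0.489	0.097
8	QC	0.4667	0.0384
9	JZ	0.4443	0.0588
10	GX	0.3557	0.0802
10	LH	0.3557	0.0588
12	DY	0.3333	0.0771
12	NC	0.3333	0.0667
12	MH	0.3333	0.0384
15	JJ	0.311	0.0588
16	FN	0.289	0.0443
16	YS	0.2887	0.0802
18	YJ	0.2667	0.0667
19	XY	0.222	0.0588
19	GN	0.222	0.0588
21	LS	0.1777	0.0447
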