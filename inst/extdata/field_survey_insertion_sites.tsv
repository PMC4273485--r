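site_id	GY	JJ	XY	SY	JZ	DY	LS	GZL	HX	TC	YJ	YX
site_1	1	1	1	1	1	1	1	1	1	1	1	1
site_2	1	1	1	1	1	1	1	1	1	1	1	1
site_3	1	1	0	0	0	1	1	0	0	0	1	0
site_4	1	1	0	0	0	0	0	0	1	0	1	0
site_5	1	0	0	0	0	0	0	0	0	0	0	0
site_6	1	0	0	0	0	0	0	0	0	0	0	0
site_7	1	0	0	0	0	1	1	1	1	1	0	1
site_8	1	1	1	1	1	1	0	1	1	0	0	1
site_9	0	1	0	0	0	1	1	0	0	0	0	0
site_10	0	0	1	0	0	0	0	0	0	0	0	0
site_11	0	0	0	1	0	0	0	0	0	0	0	0
site_12	0	0	0	1	0	0	0	0	0	0	0	0
site_13	0	0	0	1	0	0	0	1	0	0	0	0
site_14	0	0	0	0	1	0	1	0	0	1	1	0
site_15	0	0	0	0	0	1	0	0	0	0	0	0
site_16	0	0	0	0	0	0	1	0	0	0	0	0
site_17	0	0	0	0	0	0	1	1	0	0	0	0
site_18	0	0	0	0	0	0	0	1	1	0	0	0
site_19	0	0	0	0	0	0	0	0	1	0	0	0
site_20	0	0	0	0	0	0	0	0	0	1	0	0
site_21	0	0	0	0	0	0	0	0	0	0	1	0
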