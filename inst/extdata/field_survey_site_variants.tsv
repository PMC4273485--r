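site_id	tsd	itr
site_1	TTAA	CCCAGATTAGCCT
site_2	TTAA	CCCAGATTAGCCT
site_3	TTAA	CCCAGATTAGCCT
site_4	TTAA	CCCAGATTAGCCT
site_5	CTAT	CCCAGATTAGCCT
site_6	TTAA	CCCAGATTAGCCT
site_7	TTAA	CCCAGATTAGCCT
site_8	TTAA	CCCAGATTAGCCT
site_9	ATAT	CCCAGATTAGCCT
site_10	CTAA	CCCAGATTAGCCT
site_11	TTAA	CCCAGATTAGCCT
site_12	TTAA	CCCAGATTAGCCT
site_13	TTAA	CCCAGATTAGCCT
site_14	TTAA	ACCAGATTAGCCT
site_15	TTAA	CCCAGATTAGCCT
site_16	ATAT	CCCAAATTAGCCT
site_17	TTAA	CCCAGATTAGCCT
site_18	TTAA	CCCAGATTAGCCT
site_19	TTAA	CCCAGATTAGCCT
site_20	TTAA	CCCAGATTAGCCT
site_21	TTAA	CCCAGATTAGCCT
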