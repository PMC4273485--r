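region	length_mean	length_sem	nv_mean	nv_sem	rv_mean	rv_sem	letter
five_prime	613.2	0.3	3.8	0.4	0.0062	0.0007	B
orf	1518	0	8	0.8	0.0053	0.0005	B
three_prime	278	0.1	3.1	0.3	0.0113	0.0011	A
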