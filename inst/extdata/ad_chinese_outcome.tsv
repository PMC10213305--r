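SNP	EA	NEA	EAF	BETA	SE	P
rs78277894	A	G	0.336	0.08	0.101	0.428
rs2435355	C	T	0.195	0.093	0.096	0.334
rs79105258	A	C	0.257	-0.104	0.093	0.262
rs13329271	C	A	0.516	-0.108	0.084	0.2
rs56129017	T	C	0.26	-0.122	0.088	0.164
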