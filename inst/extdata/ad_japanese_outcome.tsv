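SNP	EA	NEA	EAF	BETA	SE	P
rs78277894	A	G	0.336	-0.007	0.035	0.845
rs2435355	C	T	0.195	-0.055	0.042	0.19
rs3825845	T	C	0.503	0.007	0.033	0.842
rs12151139	T	C	0.256	0.018	0.038	0.636
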