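SNP	EA	NEA	EAF	BETA	SE	P	N
rs78277894	A	G	0.336	0.04	0.006	5.63e-13	72655
rs2435355	C	T	0.195	-0.036	0.007	3.62e-8	72655
rs3825845	T	C	0.503	-0.041	0.005	6.95e-15	72655
rs12151139	T	C	0.256	0.122	0.006	4.83e-92	72655
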