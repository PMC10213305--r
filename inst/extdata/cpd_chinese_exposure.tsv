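SNP	EA	NEA	EAF	BETA	SE	P	N
rs78277894	A	G	0.336	0.04	0.006	5.63e-13	72655
rs2435355	C	T	0.195	-0.036	0.007	3.62e-8	72655
rs79105258	A	C	0.257	0.055	0.007	4.76e-17	72655
rs13329271	C	A	0.516	-0.044	0.005	2.71e-16	72655
rs56129017	T	C	0.26	0.131	0.006	2.18e-96	72655
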