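SNP_A	SNP_B	R2
rs13329271	rs3825845	0.91
rs56129017	rs12151139	0.95
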