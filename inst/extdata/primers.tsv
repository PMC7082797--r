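pair	role	name	residues	expected_length
16S	forward	16S-Forward	TTAAATTGCTGTRGTATT	438
16S	reverse	16S-Reverse	CCGGTCTGAACTCASAWC	438
COI-long	forward	Cox1-F	GGAACAATATATTTAATTTTTGG	849
COI-long	reverse	CoxI-R	ATCTATCCCTACTGTAAATATATG	849
COI-short	forward	COI-F	ATCATAAAKAYHTTGG	691
COI-short	reverse	COI-R	GGGTGACCRAARAAHCA	691
COI-LCO	forward	LCO1490	GGTCAACAAATCATAAAGATATTGG	710
COI-LCO	reverse	HCO2198	TAAACTTCAGGGTGACCAAAAAATCA	710
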