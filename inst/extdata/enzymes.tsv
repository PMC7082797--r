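name	site	cut_offset
DraI	TTTAAA	3
AluI	AGCT	2
EcoRI	GAATTC	1
EcoRV	GATATC	3
HindIII	AAGCTT	1
BamHI	GGATCC	1
BglII	AGATCT	1
PstI	CTGCAG	5
KpnI	GGTACC	5
SacI	GAGCTC	5
SmaI	CCCGGG	3
XbaI	TCTAGA	1
XhoI	CTCGAG	1
SalI	GTCGAC	1
NdeI	CATATG	2
NcoI	CCATGG	1
SphI	GCATGC	5
SspI	AATATT	3
ScaI	AGTACT	3
StuI	AGGCCT	3
AflII	CTTAAG	1
AseI	ATTAAT	2
BclI	TGATCA	1
ClaI	ATCGAT	2
BstBI	TTCGAA	2
SwaI	ATTTAAAT	4
ApoI	RAATTY	1
AvaII	GGWCC	1
HaeIII	GGCC	2
RsaI	GTAC	2
TaqI	TCGA	1
MseI	TTAA	1
MboI	GATC	0
NlaIII	CATG	4
HhaI	GCGC	3
HpaII	CCGG	1
DdeI	CTNAG	1
HinfI	GANTC	1
Tsp509I	AATT	0
AccI	GTMKAC	2
BsrGI	TGTACA	1
MfeI	CAATTG	1
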