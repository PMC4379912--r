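# Haplogroup definition fixture.
# Columns: Name, Parent, Motif (space-separated tokens, '@' = back mutation), Ancestry.
# Motifs for M24, M45, M54, M55, M82, M83, M84, M84a, M90 and M91 are SYNTHETIC
# PLACEHOLDERS (full definitions live in unavailable supplementary data).
Name	Parent	Motif	Ancestry
ROOT			
M	ROOT	489 10400 14783 15043 16223	
N	ROOT	16223 10398	
R	N	12705	
HV	R	73 14766	WestEurasian
B	R	8281-8289d 16189	EastEurasian
A	N	235 663 1736 4824 16290 16319	EastEurasian
D4	M	4883 5178A 3010 8414 14668	EastEurasian
M45	M	8618 16051 16356	SouthAsian
M24	M	14502 16234	Other
M54	M	8155 16357	Other
M54a	M54	12414 16189	Other
M55	M	12561 15930	Other
M55b	M55	16172 7972 5564 1719 1047 373 10398	Other
M82	M	5302 16148	Other
M83	M	9962 16260	Other
M84	M	6305 16327	Other
M84a	M84	1524 16215	Other
M84b	M84	16311 6260 279 152 150	Other
M90	M	6756 16164	Other
M91	M	5460 16203	Other
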