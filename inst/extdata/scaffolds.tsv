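scaffold	label	kind	sequence	length	freq_A	freq_C	freq_G	freq_T
PGPD-final	id_spacer	randomized		40	0.25	0.25	0.25	0.25
PGPD-final	RAP1_1	constant	ACACCCATAC	10	NA	NA	NA	NA
PGPD-final	spacer1	randomized		20	0.25	0.25	0.25	0.25
PGPD-final	RAP1_2	constant	ACACCCATAC	10	NA	NA	NA	NA
PGPD-final	spacer2	randomized		30	0.25	0.25	0.25	0.25
PGPD-final	GCR1_1	constant	GGCTTCCA	8	NA	NA	NA	NA
PGPD-final	spacer3	randomized		30	0.25	0.25	0.25	0.25
PGPD-final	GCR1_2	constant	GGCTTCCA	8	NA	NA	NA	NA
PGPD-final	upstream_TATA	randomized		60	0.25	0.25	0.25	0.25
PGPD-final	TATA	constant	CTATAAATA	9	NA	NA	NA	NA
PGPD-final	core	randomized		49	0.3	0.15	0.12	0.43
PGPD-final	TSS	constant	ACAAACAA	8	NA	NA	NA	NA
PGPD-final	utr	randomized		30	0.4	0.25	0	0.35
PGPD-final	flank5	flank5	TATACTAGTGAGTGACTCTCAGCAAATTAGACTTCTTCGTTTACGAAAATCCGGAAGGGTAGACTCAGCTGAAAAGAAGT	80	NA	NA	NA	NA
PGPD-final	flank3	flank3	GGTATTACATTGTCGGTTTGATCTTCTAGTGCATCCCCTTCAGGTCAATTCTTCGGAAAGACTGATGTACTCTAATCGCT	80	NA	NA	NA	NA
PZEV-design4	id_spacer	randomized		50	0.25	0.25	0.25	0.25
PZEV-design4	ZEV_1	constant	GCGTGGGCG	9	NA	NA	NA	NA
PZEV-design4	spacer1	randomized		37	0.25	0.25	0.25	0.25
PZEV-design4	ZEV_2	constant	GCGTGGGCG	9	NA	NA	NA	NA
PZEV-design4	spacer2	randomized		37	0.25	0.25	0.25	0.25
PZEV-design4	ZEV_3	constant	GCGTGGGCG	9	NA	NA	NA	NA
PZEV-design4	spacer3	randomized		30	0.25	0.25	0.25	0.25
PZEV-design4	TATA18	constant	CTATAAAAGCTATAAAAG	18	NA	NA	NA	NA
PZEV-design4	core	randomized		25	0.3	0.15	0.12	0.43
PZEV-design4	TSS	constant	ACAAACA	7	NA	NA	NA	NA
PZEV-design4	utr	randomized		15	0.4	0.25	0	0.35
PZEV-design4	flank5	flank5	AGGCTGGATTTCGTATCTTCCGACTAAGAAGATGGCCAGTGATTAGACTTTGCGTATTCACGACTGAACCCCGATCTCAG	80	NA	NA	NA	NA
PZEV-design4	flank3	flank3	GCTGTATAACGGTTATAACCGACTATCTGTAATCGTCTAGTTTAGAAATTGAACTAGGTTTCAGTCAACCAGTACTACGC	80	NA	NA	NA	NA
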