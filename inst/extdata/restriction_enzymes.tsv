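name	recognition	cut_top	cut_bottom	source
MnlI	CCTC	11	10	REBASE CCTC(7/6)
BstCI	GGCC	2	2	REBASE GG^CC (HaeIII isoschizomer)
Hpy99I	CGWCG	5	0	REBASE CGWCG(5/0)
AflIII	ACRYGT	1	5	REBASE A^CRYGT
DdeI	CTNAG	1	4	REBASE C^TNAG
NdeI	CATATG	2	4	REBASE CA^TATG
MseI	TTAA	1	3	REBASE T^TAA
SmlI	CTYRAG	1	5	REBASE C^TYRAG
Bsu36I	CCTNAGG	2	5	REBASE CC^TNAGG
BclI-HF	TGATCA	1	5	REBASE T^GATCA
NsiI-HF	ATGCAT	5	1	REBASE ATGCA^T
AseI	ATTAAT	2	4	REBASE AT^TAAT
MwoI	GCNNNNNNNGC	7	4	REBASE GCNNNNN^NNGC
NsiI	ATGCAT	5	1	REBASE ATGCA^T
SacII	CCGCGG	4	2	REBASE CCGC^GG
MspI	CCGG	1	3	REBASE C^CGG
CviQI	GTAC	1	3	REBASE G^TAC
EcoRI	GAATTC	1	5	REBASE G^AATTC
HindIII	AAGCTT	1	5	REBASE A^AGCTT
BamHI	GGATCC	1	5	REBASE G^GATCC
PstI	CTGCAG	5	1	REBASE CTGCA^G
SpeI	ACTAGT	1	5	REBASE A^CTAGT
XbaI	TCTAGA	1	5	REBASE T^CTAGA
EcoRV	GATATC	3	3	REBASE GAT^ATC
ScaI	AGTACT	3	3	REBASE AGT^ACT
KpnI	GGTACC	5	1	REBASE GGTAC^C
SacI	GAGCTC	5	1	REBASE GAGCT^C
SphI	GCATGC	5	1	REBASE GCATG^C
NheI	GCTAGC	1	5	REBASE G^CTAGC
SalI	GTCGAC	1	5	REBASE G^TCGAC
XhoI	CTCGAG	1	5	REBASE C^TCGAG
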