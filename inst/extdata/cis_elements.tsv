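element	category	pattern
ABRE	ABA-response	ACGTG
ABRE-core	ABA-response	MACGYGB
ERE	ethylene-response	AWTTCAAA
DRE/CRT	dehydration-response	RCCGAC
GCC-box	ethylene-response	GCCGCC
CAAT-box	core-promoter	CCAAT
TATA-box	core-promoter	TATAWAW
G-box	light-response	CACGTG
TGACG-motif	MeJA-response	TGACG
CGTCA-motif	MeJA-response	CGTCA
TCA-element	SA-response	CCATCTTTTT
ARE	anaerobic-induction	AAACCA
MBS	MYB-drought	CAACTG
W-box	defense-WRKY	TTGACC
AuxRR-core	auxin-response	GGTCCAT
P-box	gibberellin-response	CCTTTTG
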