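gene	mode	phenotypes
USH2A	autosomal-recessive	RP;USH
ABCA4	autosomal-recessive	STGD;RP;COD
CEP290	autosomal-recessive	LCA;RP
LRAT	autosomal-recessive	LCA;RP
CNGB3	autosomal-recessive	COD;STGD
FSCN2	autosomal-dominant	RP
PRPF31	autosomal-dominant	RP
EYS	autosomal-recessive	RP
CRB1	autosomal-recessive	RP;LCA
CRX	autosomal-dominant	LCA;COD
OFD1	x-linked	RP
RPGR	x-linked	RP;COD
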