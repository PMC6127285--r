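family_id	index_id	clin_diagnosis	features	inheritance	segregation_available	prior_gene	prior_variant	prior_gene2	prior_variant2	table2_status	table2_gene	provenance
A	II:1	STGD	macular pigment deposits; photophobia	autosomal-recessive	TRUE	NA	NA	NA	NA	Yes	ABCA4	Table2:A
B	II:1	COD	consanguinity; micronystagmus; amblyopia	autosomal-recessive	TRUE	ABCA4	m4	NA	NA	Yes	CNGB3	Table2:B
C	II:1	sRP	unilateral maculopathy; cataracts	simplex	FALSE	ABCA4	m6	NA	NA	Unknown	FSCN2	Table2:C
D	II:1	LCA	consanguinity; photophobia	autosomal-recessive	TRUE	NA	NA	NA	NA	Yes	LRAT	Table2:D
E	II:4	sRP	tunnel vision	simplex	FALSE	USH2A	M9	NA	NA	Yes	USH2A	Table2:E
F	II:3	sRP	myopia; astigmatism	simplex	FALSE	USH2A	M9	NA	NA	Yes	USH2A	Table2:F
G	II:1	sRP	incipient cataracts; tritanopia	simplex	FALSE	USH2A	M9	NA	NA	Yes	USH2A	Table2:G
H	II:3	arRP	SNHL in index attributed to a different cause (father with non-syndromic SNHL); brother with isolated arRP	autosomal-recessive	TRUE	USH2A	M9	NA	NA	Yes	USH2A	Table2:H
I	II:2	sRP	cataracts; photophobia	simplex	FALSE	USH2A	M9	NA	NA	Yes	USH2A	Table2:I
J	II:1	sRP	NA	simplex	FALSE	USH2A	M9	NA	NA	Yes	USH2A	Table2:J
K	II:1	sRP	sine pigmento	simplex	TRUE	USH2A	M9	NA	NA	Yes	USH2A	Table2:K
L	II:1	sRP	cataracts	simplex	TRUE	USH2A	M9	NA	NA	Yes	USH2A	Table2:L
M	II:1	USH	nystagmus; bilateral SNHL	autosomal-recessive	TRUE	USH2A	M17	NA	NA	Yes	USH2A	Table2:M
N	II:12	arRP	type II diabetes mellitus	autosomal-recessive	FALSE	USH2A	M17	NA	NA	Yes	USH2A	Table2:N
O	II:1	sRP	photophobia; cataracts; aphakia; glaucoma	simplex	FALSE	USH2A	M20	NA	NA	Yes	USH2A	Table2:O
P	II:9	USH	bilateral SNHL in index; two affected siblings with non-syndromic RP	autosomal-recessive	TRUE	USH2A	M20	NA	NA	Yes	USH2A	Table2:P
Q	II:4	arRP	incipient cataracts	autosomal-recessive	TRUE	USH2A	M20	NA	NA	Yes	USH2A	Table2:Q
R	II:6	USH	cataracts; nystagmus; bilateral SNHL; legal blindness	autosomal-recessive	TRUE	NA	NA	NA	NA	Yes	USH2A	Table2:R
S	II:1	sRP	myopia; astigmatism	simplex	FALSE	USH2A	m33	NA	NA	Unknown	USH2A	Table2:S
T	II:1	sRP	NA	simplex	FALSE	ABCA4	m26	CEP290	m27	No	NA	Table2:T
U	II:3	sRP	NA	simplex	FALSE	ABCA4	m28	NA	NA	No	NA	Table2:U
V	II:1	sRP	NA	simplex	FALSE	ABCA4	m29	NA	NA	No	NA	Table2:V
W	II:3	sRP	NA	simplex	FALSE	ABCA4	m6	NA	NA	No	NA	Table2:W
X	II:1	sRP	NA	simplex	FALSE	ABCA4	m6	NA	NA	No	NA	Table2:X
Y	II:1	arRP	NA	autosomal-recessive	FALSE	CEP290	m30	NA	NA	No	NA	Table2:Y
Z	II:1	sRP	NA	simplex	FALSE	CEP290	m31	NA	NA	No	NA	Table2:Z
AA	II:4	sRP	NA	simplex	FALSE	USH2A	m32	NA	NA	No	NA	Table2:AA
AB	II:1	STGD	NA	autosomal-recessive	FALSE	NA	NA	NA	NA	No	NA	Table2:AB
AC	II:3	STGD	NA	autosomal-recessive	FALSE	ABCA4	m4	NA	NA	No	NA	Table2:AC
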