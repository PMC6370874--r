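gene	human_pos	ref_aa	alt_aas
HRAS	12	G	V,D,S
HRAS	13	G	R,V,D
HRAS	61	Q	R,K,L
KRAS	12	G	D,V,C
KRAS	13	G	D
NRAS	61	Q	R,K,L
BRAF	600	V	E,K
SMO	412	L	F
SMO	535	W	L
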