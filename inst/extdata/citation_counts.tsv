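db	supp_count	body_count	shared_count
Ensembl	1292198	1152	23
RefSeq	2540260	2864	178
InterPro	564956	639	77
UniProt	2972519	9387	540
Pfam	924624	2968	435
RefSNP	2443679	31061	3849
ENA	3390319	125534	4167
PDBe	197850	44269	2805
ArrayExpress	2377	1565	53
OMIM	2400	2779	19
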