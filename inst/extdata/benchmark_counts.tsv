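db	evaluation	version	tp	fp	fn
ENA	automatic	new	276	10	170
ENA	automatic	old	267	7	181
ENA	manual	new	286	0	170
ENA	manual	old	274	0	181
UniProt	automatic	new	574	28	39
UniProt	automatic	old	569	8	39
UniProt	manual	new	601	1	39
UniProt	manual	old	577	0	39
PDBe	automatic	new	568	32	12
PDBe	automatic	old	529	30	50
PDBe	manual	new	620	0	12
PDBe	manual	old	559	0	50
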