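target	fwd_name	fwd_seq	rev_name	rev_seq	conc_uM	size_bp	in_multiplex
Pardosa spp.	Pard-sp-S238	CTGTTTATCCTCCTTTAGCATCTAC	Pard-sp-A239	AGCCCCAGCTAAATGAAGAG	0.2	86	TRUE
Nebria rufescens	Neb-ruf-S249	TCAGTCGGAATTACTGCATTAC	Neb-ruf-A250	GGGTCAAAGAAAGTTGTATTTAAG	0.1	107	TRUE
Oreonebria castanea	Ore-cas-S240	CTCTGTTGACTTAGCTATTTTCAGA	Ore-cas-A241	AATAAAGGTATTCGATCAAAGGA	0.2	129	TRUE
Mitopus glacialis	Mit-gla-S243	TATACCCCCCTCTATCAAGAAAT	Mit-gla-A244	TACCTTGTGTTCGTATGTTGATG	0.1	144	TRUE
Nebria jockischii	Neb-joc-S242	GTGAACAGTTTACCCTCCACTG	Neb-joc-A243	TTCGGTCAAAAGTTATACCAATT	0.1	167	TRUE
Nebria germari	Neb-ger-S241	CGAATGAATAATATAAGATTTTGACTT	Neb-ger-A242	AGCCCCTAAAATTGAAGAAATA	0.4	198	TRUE
Collembola	Col3F	GGACGATYTTRTTRGTTCGT	Col-gen-A246	TTTCACCTCTAACGTCGCAG	0.4	228	TRUE
Nebria germari	Neb-ger-S256	ATTAGGAAACCCTGGGTCC	Neb-ger-A255	AGTTAATGAAGGGGGAAGAAG	1	210	FALSE
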