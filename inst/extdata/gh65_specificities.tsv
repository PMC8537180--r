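ec	enzyme	abbreviation	substrate	product
2.4.1.8	Maltose phosphorylase	MP	Glc-a1,4-Glc	bGlc1P
2.4.1.64	Trehalose phosphorylase	TP	Glc-a1,1a-Glc	bGlc1P
2.4.1.216	Trehalose-6-phosphate phosphorylase	T6PP	Glc-a1,1a-Glc6P	bGlc1P
2.4.1.230	Kojibiose phosphorylase	KP	Glc-a1,2-Glc	bGlc1P
2.4.1.279	Nigerose phosphorylase	NP	Glc-a1,3-Glc	bGlc1P
2.4.1.282	3-O-alpha-glucosyl-L-rhamnose phosphorylase	GRP	Glc-a1,3-L-Rham	bGlc1P
2.4.1.332	2-O-alpha-glucosylglycerol phosphorylase	GGP	Glc-a1,2-glycerol	bGlc1P
2.4.1.334	alpha-1,3-oligoglucan phosphorylase	oligoNP	Glc-a1,3-oligoglucan	bGlc1P
3.2.1.28	Trehalose hydrolase (trehalase)	TH	Glc-a1,1a-Glc	Glc
3.2.1.107	Protein-alpha-glucosyl-1,2-beta-galactosyl-L-hydroxylysine alpha-glucosidase	PGGHG	Glc-a1,2-Gal-b1,5-Hyl	Glc
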