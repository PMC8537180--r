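specificity_label	motif_string	note
MP	KV[MF]NES	maltose phosphorylase consensus over positions 64/392/394/402/416/585
KP	EEAPxx	kojibiose phosphorylase; the two free positions make this a 4-position constraint
TP	TRIGPP	trehalose phosphorylase branch motif
oligoNP	FAITQA	alpha-1,3-oligoglucan phosphorylase branch motif
T6PP	DQGQDE	trehalose-6-phosphate phosphorylase branch motif
unknown	SVSWRQ	single-sequence motif of uncharacterized subgroup 7
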