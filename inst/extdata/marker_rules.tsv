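category	family	field	pattern	exemplar	min_identity	required
MOB	MOBQ	gene	^mobA$	.	.	.
MOB	MOBF	gene	^traI$	.	.	.
MOB	MOBP	gene	^virD2$	.	.	.
MPF	T4SS	gene	^virB1$	.	.	TRUE
MPF	T4SS	gene	^virB2$	.	.	TRUE
MPF	T4SS	gene	^virB3$	.	.	TRUE
MPF	T4SS	gene	^virB4$	.	.	TRUE
MPF	T4SS	gene	^virB5$	.	.	TRUE
MPF	T4SS	gene	^virB6$	.	.	TRUE
MPF	T4SS	gene	^virB7$	.	.	TRUE
MPF	T4SS	gene	^virB8$	.	.	TRUE
MPF	T4SS	gene	^virB9$	.	.	TRUE
MPF	T4SS	gene	^virB10$	.	.	TRUE
MPF	T4SS	gene	^virB11$	.	.	TRUE
MPF	T4SS	gene	^virD4$	.	.	TRUE
TA_toxin	relBE	gene	^relE	.	.	.
TA_antitoxin	relBE	gene	^relB	.	.	.
TA_toxin	HipAB	gene	^hipA	.	.	.
TA_antitoxin	HipAB	gene	^hipB	.	.	.
TA_toxin	MazFE	gene	^mazF	.	.	.
TA_antitoxin	MazFE	gene	^mazE	.	.	.
TA_toxin	vapBC	gene	^vapC	.	.	.
TA_antitoxin	vapBC	gene	^vapB	.	.	.
TA_toxin	parED	gene	^parE[0-9]*$	.	.	.
TA_antitoxin	parED	gene	^parD	.	.	.
RM_REase	TypeI	gene	^hsdR	.	.	.
RM_MTase	TypeI	gene	^hsdM	.	.	.
RM_REase	TypeII	product	[Tt]ype II restriction endonuclease	.	.	.
RM_MTase	TypeII	product	[Tt]ype II (DNA )?methyltransferase	.	.	.
RM_REase	TypeIII	gene	^res$	.	.	.
RM_MTase	TypeIII	gene	^mod$	.	.	.
RM_REase	TypeIV	gene	^mcr[BC]	.	.	.
RM_MTase	TypeIV	gene	^mrr	.	.	.
essential_single_copy	ligA	product	DNA ligase	.	.	.
essential_single_copy	dnaN	product	polymerase III.*beta	.	.	.
essential_single_copy	parC	product	topoisomerase IV subunit A	.	.	.
essential_single_copy	parE	product	topoisomerase IV subunit B	.	.	.
essential_single_copy	recA	product	[Rr]ecombination.*RecA|RecA protein	.	.	.
essential_single_copy	tilS	product	lysidine synth	.	.	.
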