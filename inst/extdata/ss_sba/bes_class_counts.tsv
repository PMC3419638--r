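class_label	aligned_bes	chromosome	orientation	span_band_kb	type	n_bacs
C1	2	same	opposite_in	20-300	concordant	42
C2	2	same	same	20-300	discordant	1
C3	2	same	opposite_in	>300	discordant	16
C4	2	same	same	>300	discordant	12
C5	2	same	opposite_out	>300	discordant	15
C6	2	different	NA	NA	discordant	9
C7	1	NA	NA	NA	single	10
C8	1	NA	NA	NA	multiple	65
C9	0	NA	NA	NA	none	22
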