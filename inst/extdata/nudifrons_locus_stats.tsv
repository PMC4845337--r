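locus	sizeMin	sizeMax	na	ho	he
Ln_22268	108	108	1	0	0
Ln_22517	251	263	4	0.29	0.26
Ln_23194	92	92	1	0	0
Ln_32298	275	275	1	0	0
Ln_34878	126	138	7	0.86	0.8
Ln_35217	242	246	3	0.33	0.42
Ln_36100	258	264	2	0.1	0.09
Ln_36156	186	244	17	1	0.92
Ln_40551	291	329	6	0.52	0.6
Ln_41246	89	89	1	0	0
Ln_41281	314	320	2	0.1	0.09
Ln_42016	127	139	7	0.62	0.73
Ln_42233	212	242	2	0.1	0.09
Ln_42701	107	107	1	0	0
Ln_45257	98	100	2	0.05	0.13
Ln_45589	132	146	4	0.76	0.64
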