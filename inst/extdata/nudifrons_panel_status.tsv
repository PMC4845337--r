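locus	nudifrons	squamifrons	larseni
Ln_22268	M	M	M
Ln_22517	P	M	F
Ln_23194	M	P	P
Ln_32298	M	M	M
Ln_34878	P	F	F
Ln_35217	P	P	P
Ln_36100	P	M	P
Ln_36156	P	P	P
Ln_40551	P	P	P
Ln_41246	M	F	F
Ln_41281	P	P	P
Ln_42016	P	P	P
Ln_42233	P	M	P
Ln_42701	M	M	M
Ln_45257	P	P	P
Ln_45589	P	P	P
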