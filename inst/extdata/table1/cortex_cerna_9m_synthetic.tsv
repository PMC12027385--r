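# SYNTHETIC ceRNA direction calls for the 9-month stage (no circRNA
# class at this stage; the builder handles absent classes). Identifiers
# are synthetic.
feature_id	rna_class	direction
sgene01	mRNA	down
sgene02	mRNA	up
sgene03	mRNA	up
sgene04	mRNA	down
sgene05	mRNA	ns
sgene06	mRNA	up
sgene07	mRNA	down
sgene08	mRNA	down
sgene09	mRNA	up
slnc01	lncRNA	down
slnc02	lncRNA	up
slnc03	lncRNA	ns
slnc04	lncRNA	up
slnc05	lncRNA	down
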