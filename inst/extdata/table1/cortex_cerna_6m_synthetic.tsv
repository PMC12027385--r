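# SYNTHETIC ceRNA direction calls for the 6-month stage: stand-in for
# the cortex mRNA/lncRNA/circRNA differential-expression tables, which
# are not printed in the source publication. Identifiers are synthetic.
feature_id	rna_class	direction
sgene01	mRNA	up
sgene02	mRNA	up
sgene03	mRNA	down
sgene04	mRNA	down
sgene05	mRNA	up
sgene06	mRNA	ns
sgene07	mRNA	down
sgene08	mRNA	up
slnc01	lncRNA	up
slnc02	lncRNA	down
slnc03	lncRNA	up
slnc04	lncRNA	ns
slnc05	lncRNA	down
scirc01	circRNA	up
scirc02	circRNA	down
scirc03	circRNA	ns
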