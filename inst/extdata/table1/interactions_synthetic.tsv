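# SYNTHETIC CLIP-supported miRNA-target interaction table covering the
# fixture seed miRNAs. mmu-miR-1983 and mmu-miR-99b-3p are deliberately
# absent, mirroring seeds for which the interaction database reports no
# CLIP-supported partner.
mirna_id	target_id	target_class	clip_support
mmu-miR-339-3p	sgene03	mRNA	4
mmu-miR-339-3p	sgene05	mRNA	2
mmu-miR-339-3p	slnc02	lncRNA	1
mmu-miR-369-5p	sgene03	mRNA	6
mmu-miR-369-5p	sgene04	mRNA	3
mmu-miR-369-5p	sgene07	mRNA	2
mmu-miR-369-5p	slnc05	lncRNA	5
mmu-miR-369-5p	scirc02	circRNA	1
mmu-miR-450b-5p	sgene04	mRNA	2
mmu-miR-450b-5p	slnc02	lncRNA	3
mmu-miR-450b-5p	scirc02	circRNA	2
mmu-miR-881-3p	sgene07	mRNA	1
mmu-miR-881-3p	sgene06	mRNA	1
mmu-miR-31-5p	sgene01	mRNA	7
mmu-miR-31-5p	sgene02	mRNA	2
mmu-miR-31-5p	slnc01	lncRNA	4
mmu-miR-31-5p	scirc01	circRNA	2
mmu-miR-122-5p	sgene05	mRNA	9
mmu-miR-122-5p	sgene08	mRNA	3
mmu-miR-122-5p	slnc03	lncRNA	2
mmu-miR-24-3p	sgene01	mRNA	8
mmu-miR-24-3p	sgene04	mRNA	5
mmu-miR-24-3p	sgene08	mRNA	2
mmu-miR-24-3p	slnc05	lncRNA	3
mmu-miR-149-5p	sgene07	mRNA	6
mmu-miR-149-5p	sgene08	mRNA	4
mmu-miR-149-5p	slnc01	lncRNA	2
mmu-miR-187-3p	sgene04	mRNA	3
mmu-miR-187-3p	slnc05	lncRNA	1
mmu-miR-434-5p	sgene01	mRNA	2
mmu-miR-434-5p	sgene07	mRNA	3
mmu-miR-467a-5p	sgene08	mRNA	2
mmu-miR-467a-5p	slnc01	lncRNA	1
mmu-miR-666-5p	sgene04	mRNA	2
mmu-miR-1198-5p	sgene07	mRNA	4
mmu-miR-1198-5p	sgene08	mRNA	1
mmu-miR-3074-5p	sgene01	mRNA	5
mmu-miR-3074-5p	slnc05	lncRNA	2
mmu-miR-10b-5p	sgene02	mRNA	6
mmu-miR-10b-5p	sgene03	mRNA	3
mmu-miR-10b-5p	sgene06	mRNA	2
mmu-miR-10b-5p	slnc02	lncRNA	1
mmu-miR-34b-5p	sgene02	mRNA	4
mmu-miR-34b-5p	sgene09	mRNA	2
mmu-miR-34c-5p	sgene02	mRNA	7
mmu-miR-34c-5p	sgene06	mRNA	3
mmu-miR-34c-5p	slnc04	lncRNA	2
mmu-miR-340-5p	sgene09	mRNA	5
mmu-miR-340-5p	slnc04	lncRNA	2
mmu-miR-369-3p	sgene03	mRNA	2
mmu-miR-369-3p	sgene06	mRNA	4
mmu-miR-499-5p	sgene09	mRNA	1
mmu-miR-499-5p	slnc02	lncRNA	2
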