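sterm01	synaptic signaling (synthetic)	sgene01	sgene02	sgene03	sgene04
sterm02	cytoskeleton organization (synthetic)	sgene05	sgene06	sgene07	sgene08
sterm03	vesicle transport (synthetic)	sgene01	sgene05	sgene09	slnc01
sterm04	noncoding regulation (synthetic)	slnc01	slnc02	slnc03	slnc04	slnc05
sterm05	broad background (synthetic)	sgene01	sgene02	sgene03	sgene04	sgene05	sgene06	sgene07	sgene08	sgene09	slnc01	slnc02	slnc03	slnc04	slnc05	scirc01	scirc02	scirc03
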