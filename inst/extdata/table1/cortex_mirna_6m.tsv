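# APP/PSEN1 mouse cortex miRNA direction calls at 6 months.
# mean_ctrl/mean_case are the published normalized expression values
# (median-of-ratios scale, WT vs APP/PS1) for the concordant miRNAs;
# decoy rows (non-concordant or not significant) carry synthetic means.
feature_id	rna_class	mean_ctrl	mean_case	direction
mmu-miR-339-3p	miRNA	86	110	up
mmu-miR-369-5p	miRNA	2999	3361	up
mmu-miR-450b-5p	miRNA	10	18	up
mmu-miR-881-3p	miRNA	17	33	up
mmu-miR-1983	miRNA	335	423	up
mmu-miR-31-5p	miRNA	195	160	down
mmu-miR-122-5p	miRNA	42	24	down
mmu-miR-185-5p	miRNA	50	80	up
mmu-miR-500-3p	miRNA	20	35	up
mmu-miR-204-5p	miRNA	90	60	down
mmu-miR-24-3p	miRNA	21000	21200	ns
mmu-miR-34c-5p	miRNA	7000	7050	ns
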