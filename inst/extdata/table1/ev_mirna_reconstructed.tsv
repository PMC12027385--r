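# Neuron-derived EV miRNA cargo direction calls, RECONSTRUCTED:
# the source study publishes only the concordant result per stage, so EV
# directions are the ones implied by the concordance rule; expression
# means in this file are synthetic placeholders satisfying the direction
# invariant. Decoy rows carry non-concordant labels.
feature_id	rna_class	mean_ctrl	mean_case	direction
mmu-miR-339-3p	miRNA	100	210	up
mmu-miR-369-5p	miRNA	2800	3500	up
mmu-miR-450b-5p	miRNA	12	25	up
mmu-miR-881-3p	miRNA	15	40	up
mmu-miR-1983	miRNA	300	450	up
mmu-miR-24-3p	miRNA	20000	24500	up
mmu-miR-99b-3p	miRNA	700	950	up
mmu-miR-149-5p	miRNA	2100	2900	up
mmu-miR-187-3p	miRNA	1300	1700	up
mmu-miR-434-5p	miRNA	98000	120000	up
mmu-miR-467a-5p	miRNA	2600	3300	up
mmu-miR-666-5p	miRNA	1100	1500	up
mmu-miR-1198-5p	miRNA	1200	1460	up
mmu-miR-3074-5p	miRNA	20500	24100	up
mmu-miR-31-5p	miRNA	210	150	down
mmu-miR-122-5p	miRNA	45	22	down
mmu-miR-10b-5p	miRNA	230	155	down
mmu-miR-34b-5p	miRNA	33	11	down
mmu-miR-34c-5p	miRNA	7200	4700	down
mmu-miR-340-5p	miRNA	7800	6100	down
mmu-miR-369-3p	miRNA	1700	1420	down
mmu-miR-499-5p	miRNA	190	150	down
mmu-miR-185-5p	miRNA	5200	2600	down
mmu-miR-204-5p	miRNA	400	640	up
mmu-miR-132-3p	miRNA	900	910	ns
mmu-miR-700-5p	miRNA	60	130	up
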