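protein	drug	pdb_id	resistant	non_resistant
ABL1	Imatinib	1OPJ	31	36
ALK	Alectinib	3AOX	24	50
BTK	Ibrutinib	5P9I	4	36
EGFR	Osimertinib	4ZAU	15	54
ESR1	Raloxifene	1ERR	6	23
FLT3	Quizartinib	4RT7	5	48
KIT	Imatinib	1T46	21	51
MAP2K1	PD0325901	3VVH	2	31
PDGFRA	Sunitinib	6JOK	1	65
SMO	Vismodegib	5L7I	17	42
MET	Crizotinib	2WGJ	7	41
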