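model	stage	most_favoured	additional_allowed	generously_allowed	disallowed	printed_most_favoured_pct	consistent
P_falciparum	before	89	21	4	3	76.1	TRUE
P_falciparum	after	84	33	0	0	71.9	FALSE
P_furiosus	before	62	40	1	6	56.9	TRUE
P_furiosus	after	84	33	0	0	71.8	TRUE
N_crassa	before	65	50	4	3	52.0	FALSE
N_crassa	after	69	56	0	0	55.5	FALSE
A_thaliana	before	82	45	7	3	60.7	FALSE
A_thaliana	after	86	49	0	0	63.7	TRUE
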