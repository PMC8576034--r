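gene	n_sites	alt_case	ref_case	alt_control	ref_control
TMEM232	12	20	172	50	142
CAMK4	6	23	73	24	72
EPB41L4A	19	155	149	157	147
LOC102467214	6	47	49	46	50
MAN2A1	13	118	90	118	90
SLC25A46	11	34	142	45	131
NREP	7	6	106	5	107
STARD4	2	4	28	7	25
TSLP	9	24	120	20	124
WDR36	21	64	272	67	269
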