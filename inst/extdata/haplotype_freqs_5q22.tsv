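label	allele_string	freq_case_pct	freq_control_pct	common
H1	NA	0.34	0.18	FALSE
H6	NA	0.1	0.45	FALSE
H14	ACCTAGCGAT	6.8	5.52	TRUE
H15	GCCTAG-GAT	0.16	0.94	TRUE
H27	NA	0.55	0.47	FALSE
H30	NA	0.33	0.16	FALSE
H39	NA	0.56	0.25	FALSE
H43	GTCTAGCGAT	5.39	4.63	TRUE
H47	GCCT-GCGAT	0.09	0.57	TRUE
H53	NA	0.01	0.09	FALSE
H54	GCCCAGCGAT	0.55	0.56	TRUE
H56	GCTTAGCGAT	4.12	3.72	TRUE
H62	GCCTAGCGAT	23.19	24.15	TRUE
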