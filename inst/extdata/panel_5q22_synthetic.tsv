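id	ref_allele	alt_allele	is_indel	position
rs10067777	G	A	FALSE	109100500
rs7701890	C	T	FALSE	109400220
rs13360927	C	T	FALSE	110200115
rs13361382	T	C	FALSE	110300880
rs5870408	A	-	TRUE	110500432
rs140764268	G	-	TRUE	110700215
rs11357450	C	-	TRUE	110881200
rs35639206	G	-	TRUE	111200350
rs137936676	A	-	TRUE	111500620
rs10617471	T	-	TRUE	111800040
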