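module	start	end	length	five_re	three_re	clones_sequenced	pct_correct
1	8532	9117	586	(XhoI)	AvrII	3	100
2	9114	9800	687	XbaI	BamHI	3	67
3	9795	10573	779	BamHI	AvrII	3	67
4	10570	11208	639	SpeI	XhoI	3	100
5	11205	12491	1287	SalI	(NcoI)	4	100
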