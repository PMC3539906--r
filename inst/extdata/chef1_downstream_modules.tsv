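module	start	end	length	five_re	three_re	clones_sequenced	pct_correct
1	14545	15157	613	(NheI)	XbaI	4	75
2	15154	15908	755	NheI	AvrII	3	100
3	15905	16644	740	NheI	AvrII	3	100
4	16639	17327	689	AvrII	SacI	3	100
5	17322	18019	698	SacI	BamHI	4	100
6	18016	18794	780	BclI	(XhoI)	5	60
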