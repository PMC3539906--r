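name	site	cohesive_end	end_type	dam	dcm
XhoI	CTCGAG	TCGA	five_prime	FALSE	FALSE
XbaI	TCTAGA	CTAG	five_prime	FALSE	FALSE
BamHI	GGATCC	GATC	five_prime	FALSE	FALSE
SalI	GTCGAC	TCGA	five_prime	FALSE	FALSE
EcoRI	GAATTC	AATT	five_prime	FALSE	FALSE
NheI	GCTAGC	CTAG	five_prime	FALSE	FALSE
BclI	TGATCA	GATC	five_prime	TRUE	FALSE
SpeI	ACTAGT	CTAG	five_prime	FALSE	FALSE
SacI	GAGCTC	AGCT	three_prime	FALSE	FALSE
AvrII	CCTAGG	CTAG	five_prime	FALSE	FALSE
NcoI	CCATGG	CATG	five_prime	FALSE	FALSE
PciI	ACATGT	CATG	five_prime	FALSE	FALSE
AhlI	ACTAGT	CTAG	five_prime	FALSE	FALSE
Psp124BI	GAGCTC	AGCT	three_prime	FALSE	FALSE
Ksp22I	TGATCA	GATC	five_prime	TRUE	FALSE
AspA2I	CCTAGG	CTAG	five_prime	FALSE	FALSE
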