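# Five tumors from one family segregating the BRCA1 c.4963T>C (p.Ser1655Pro)
# variant: tumor variant-allele fractions with pathologist-estimated tumor
# cellularity. VAFs are encoded as alt/total read depths out of 100 so the
# published percentages are preserved exactly.
sample_id	variant_id	variant_class	effect	tissue	method	cellularity	alt_depth	total_depth	germline_vaf
F1-P1-T1	c.4963T>C	VUS	MISSENSE	BREAST	NGS	0.60	65	100	0.5
F1-P1-T2	c.4963T>C	VUS	MISSENSE	BREAST	NGS	0.30	49	100	0.5
F1-P2-T1	c.4963T>C	VUS	MISSENSE	BREAST	NGS	0.70	88	100	0.5
F1-P2-T2	c.4963T>C	VUS	MISSENSE	OVARY	NGS	0.90	67	100	0.5
F1-P3-T1	c.4963T>C	VUS	MISSENSE	BREAST	NGS	0.90	70	100	0.5
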