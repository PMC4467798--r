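##fileformat=VCFv4.2
##reference=TAS2R38_synthetic
#CHROM	POS	ID	REF	ALT
TAS2R38	145	rs713598	C	G
TAS2R38	785	rs1726866	C	T
TAS2R38	886	rs10246939	G	A
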