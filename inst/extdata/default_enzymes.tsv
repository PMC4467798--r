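# restriction enzyme catalog: name, IUPAC recognition site, top-strand cut offset
name	site	cut_offset
HaeIII	GGCC	2
Eco47III	AGCGCT	3
RsaI	GTAC	2
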