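sample	barcode	fprimer	rprimer
sampleA	ACGT	AGGTT	TGCAA
sampleB	TGCA	AGGTT	TGCAA
sampleC	GGAT	5
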