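pathway_id	node_id	node_type
toy_signal	RTK	protein
toy_signal	CPLX1	complex
toy_signal	CPLX2	complex
toy_signal	TF	protein
toy_signal	CMPD	compound
toy_cascade	FAM	family
toy_cascade	K1	protein
toy_cascade	K2	protein
toy_cascade	MIR	mirna
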