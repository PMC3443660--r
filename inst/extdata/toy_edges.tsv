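pathway_id	source_node_id	target_node_id
toy_signal	RTK	CPLX1
toy_signal	RTK	CPLX2
toy_signal	CPLX1	TF
toy_signal	CPLX2	TF
toy_signal	CMPD	RTK
toy_cascade	FAM	K1
toy_cascade	K1	K2
toy_cascade	MIR	K2
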