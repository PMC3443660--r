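pathway_id	node_id	gene_id
toy_signal	RTK	g1
toy_signal	CPLX1	g2
toy_signal	CPLX1	g3
toy_signal	CPLX2	g2
toy_signal	CPLX2	g4
toy_signal	TF	g5
toy_cascade	FAM	g6
toy_cascade	FAM	g7
toy_cascade	K1	g8
toy_cascade	K2	g5
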