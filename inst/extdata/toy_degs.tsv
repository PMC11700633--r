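gene_id	log2FC	FDR
pnp4a	1.5	0.01
alkal2a	3.0	0.05
ltk	1.0	0.01
myh7	-1.2	0.01
actb	-0.9	0.001
tfec	2.4	0.049
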