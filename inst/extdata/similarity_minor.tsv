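rna	metazoa_minor
U11	0.63
U12	0.58
U4atac	0.48
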