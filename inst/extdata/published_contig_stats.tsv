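stat	mean	max	min
contig_length_bp	495	2065	118
reads_per_contig	8.8	2460	1
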