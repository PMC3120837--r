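feature	ME	P	PS	total
reads_raw	147870	176175	184685	508730
reads_assembled	68690	83692	108095	260477
mean_read_length	361	357	347	354
n_contigs	8533	11353	14883	29682
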