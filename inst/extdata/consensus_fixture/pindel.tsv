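contig	pos	ref	alt	sample_id	caller	depth	alt_count
ctg	15	AA	A	S1	pindel	38	9
ctg	20	A	AT	S1	pindel	30	7
ctg	4	T	A	S1	pindel	21	5
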