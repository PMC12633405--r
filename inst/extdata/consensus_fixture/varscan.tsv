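contig	pos	ref	alt	sample_id	caller	depth	alt_count
ctg	6	C	T	S1	varscan	28	9
ctg	19	C	T	S1	varscan	9	4
ctg	23	C	T	S1	varscan	20	2
ctg	2	C	A	S1	varscan	45	18
ctg	11	C	T	S1	varscan	33	12
ctg	27	C	T	S1	varscan	60	25
ctg	10	T	C	S1	varscan	NA	NA
ctg	4	T	A	S1	varscan	20	6
ctg	25	T	G	S1	varscan	90	35
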