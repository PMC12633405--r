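contig	pos	ref	alt	sample_id	caller	depth	alt_count
ctg	6	C	T	S1	mutect2	30	10
ctg	6	C	G	S1	mutect2	40	12
ctg	19	C	T	S1	mutect2	10	5
ctg	23	C	T	S1	mutect2	25	2
ctg	2	C	A	S1	mutect2	50	20
ctg	11	C	T	S1	mutect2	40	15
ctg	12	CA	C	S1	mutect2	44	12
ctg	20	A	AT	S1	mutect2	35	8
ctg	10	T	C	S1	mutect2	NA	NA
ctg	4	T	A	S1	mutect2	22	6
ctg	25	T	G	S1	mutect2	100	40
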