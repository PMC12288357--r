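# twinmeth annotation v1 (published cg06500161/ABCG1 coordinates; remaining rows synthetic)
cpg	chr	position	gene	locus	enhancer
cg06500161	21	43656587	ABCG1	Body	TRUE
cg00000001	1	1234567	GENE1	TSS1500	FALSE
cg00000002	2	7654321	GENE2	5'UTR	TRUE
cg00000003	7	11223344	GENE3	Body	FALSE
cg00000004	10	55667788		unannotated	FALSE
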