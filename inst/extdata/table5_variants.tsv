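# Constitutional variant sites of the MutaMouse transgene monomer
# (pos on the 47,588 bp monomer contig; alt comma-separated when multi-allelic;
# indel alleles anchored VCF-style)
pos	ref	alt
137	AG	A
14266	C	CG
19670	T	A
19673	A	C
23445	G	C
23481	A	G
24583	TA	T
25143	A	G
27867	T	C
28598	G	A
28599	T	A
28817	A	T
30349	CT	C
31786	A	G
33016	T	C
34070	A	G
34331	T	C
44629	T	C,A,G
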