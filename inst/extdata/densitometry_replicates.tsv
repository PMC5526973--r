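gene	condition	bio_rep	value
CDH4	hsa	I	0.431
CDH4	hsa	II	0.650
CDH4	ptr	I	0.952
CDH4	ptr	II	1.171
CDH4	mmu	I	1.018
CDH4	mmu	II	1.045
CDH4	cja	I	1.336
CDH4	cja	II	1.213
MSN	hsa	I	0.051
MSN	hsa	II	0.116
MSN	ptr	I	0.695
MSN	ptr	II	0.728
MSN	mmu	I	2.046
MSN	mmu	II	1.694
MSN	cja	I	2.562
MSN	cja	II	2.228
BACE2	hsa	I	0.358
BACE2	hsa	II	0.348
BACE2	ptr	I	0.749
BACE2	ptr	II	0.731
BACE2	mmu	I	1.071
BACE2	mmu	II	0.989
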