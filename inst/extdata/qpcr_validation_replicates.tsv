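gene	condition	bio_rep	value
BACE2	hsa	I	0.177
BACE2	hsa	II	0.211
BACE2	ptr	I	1.875
BACE2	ptr	II	1.973
BACE2	mmu	I	1.598
BACE2	mmu	II	1.999
BACE2	cja	I	0.595
BACE2	cja	II	0.497
DCDC2	hsa	I	0.289
DCDC2	hsa	II	0.230
DCDC2	ptr	I	0.562
DCDC2	ptr	II	0.879
DCDC2	mmu	I	0.433
DCDC2	mmu	II	0.474
DCDC2	cja	I	0.889
DCDC2	cja	II	0.800
CDH4	hsa	I	0.284
CDH4	hsa	II	0.387
CDH4	ptr	I	1.128
CDH4	ptr	II	1.661
CDH4	mmu	I	3.003
CDH4	mmu	II	3.565
CDH4	cja	I	2.437
CDH4	cja	II	2.154
FOXL1	hsa	I	0.378
FOXL1	hsa	II	0.308
FOXL1	ptr	I	3.404
FOXL1	ptr	II	2.443
FOXL1	mmu	I	3.140
FOXL1	mmu	II	3.661
FOXL1	cja	I	2.235
FOXL1	cja	II	1.790
GABRE	hsa	I	0.014
GABRE	hsa	II	0.012
GABRE	ptr	I	0.423
GABRE	ptr	II	0.455
GABRE	mmu	I	0.606
GABRE	mmu	II	0.562
GABRE	cja	I	0.361
GABRE	cja	II	0.348
MSN	hsa	I	0.111
MSN	hsa	II	0.180
MSN	ptr	I	1.217
MSN	ptr	II	1.825
MSN	mmu	I	0.981
MSN	mmu	II	1.237
MSN	cja	I	1.391
MSN	cja	II	1.474
MYH8	hsa	I	0.253
MYH8	hsa	II	0.293
MYH8	ptr	I	1.369
MYH8	ptr	II	1.620
MYH8	mmu	I	1.337
MYH8	mmu	II	1.285
MYH8	cja	I	1.974
MYH8	cja	II	2.067
MYH13	hsa	I	0.044
MYH13	hsa	II	0.049
MYH13	ptr	I	1.011
MYH13	ptr	II	0.897
MYH13	mmu	I	0.565
MYH13	mmu	II	0.536
MYH13	cja	I	0.808
MYH13	cja	II	0.826
NURR1	hsa	I	0.092
NURR1	hsa	II	0.131
NURR1	ptr	I	2.742
NURR1	ptr	II	2.331
NURR1	mmu	I	3.386
NURR1	mmu	II	3.915
NURR1	cja	I	0.840
NURR1	cja	II	1.007
PHOX2B	hsa	I	0.091
PHOX2B	hsa	II	0.083
PHOX2B	ptr	I	0.942
PHOX2B	ptr	II	0.598
PHOX2B	mmu	I	0.877
PHOX2B	mmu	II	0.447
PHOX2B	cja	I	2.598
PHOX2B	cja	II	3.094
PTPRQ	hsa	I	0.147
PTPRQ	hsa	II	0.131
PTPRQ	ptr	I	0.401
PTPRQ	ptr	II	0.300
PTPRQ	mmu	I	1.357
PTPRQ	mmu	II	1.119
PTPRQ	cja	I	0.331
PTPRQ	cja	II	0.377
SEBOX	hsa	I	4.423
SEBOX	hsa	II	4.172
SEBOX	ptr	I	0.105
SEBOX	ptr	II	0.143
SEBOX	mmu	I	0.143
SEBOX	mmu	II	0.169
SEBOX	cja	I	0.153
SEBOX	cja	II	0.182
TMEM200A	hsa	I	0.124
TMEM200A	hsa	II	0.088
TMEM200A	ptr	I	1.110
TMEM200A	ptr	II	0.839
TMEM200A	mmu	I	1.567
TMEM200A	mmu	II	1.207
TMEM200A	cja	I	0.326
TMEM200A	cja	II	0.483
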