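allele	BlackAfrican	Caucasian	Coloured	Indian
*1	25.7	30.0	30.0	45.0
*2	8.6	15.0	15.0	30.0
*4	0.0	20.0	15.0	0.0
*5	10.7	5.0	5.0	0.0
*10	5.7	5.0	5.0	0.0
*14	0.0	0.0	0.0	0.0
*16	0.0	0.0	0.0	0.0
*17	25.7	0.0	10.0	0.0
*22	0.0	0.0	0.0	5.0
*25	0.0	0.0	0.0	0.0
*29	4.3	0.0	5.0	0.0
*30	0.0	0.0	0.0	0.0
*33	0.0	5.0	0.0	0.0
*35	0.0	5.0	0.0	0.0
*36	0.0	0.0	0.0	0.0
*40	3.6	0.0	0.0	0.0
*41	0.7	15.0	5.0	10.0
*43	0.7	0.0	5.0	5.0
*45B	5.7	0.0	0.0	0.0
*46	0.7	0.0	0.0	0.0
*56B	0.7	0.0	0.0	0.0
*59	0.0	0.0	0.5	0.0
*64	0.0	0.0	0.0	0.0
*65	0.0	0.0	0.0	0.0
*73	0.0	0.0	0.0	0.0
*74	0.0	0.0	0.0	0.0
*84	0.7	0.0	0.0	0.0
*85	0.7	0.0	0.0	0.0
*86	0.0	0.0	0.0	5.0
*1xN	0.0	0.0	0.0	0.0
*2xN	0.7	0.0	0.0	0.0
*4xN	2.9	0.0	0.0	0.0
alleles_identified	140	20	20	20
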