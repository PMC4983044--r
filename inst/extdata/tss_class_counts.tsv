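class	Chr	pHV1	pHV3	pHV4
all	3248	149	510	842
forward	1646	69	263	414
reverse	1602	80	247	428
protein_coding	1421	32	170	228
leaderless	1068	19	106	136
leadered	353	13	64	92
known_rna	92	2	6	6
novel	1735	115	334	608
intergenic_novel	239	14	57	85
antisense	764	61	126	293
internal	732	40	151	230
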