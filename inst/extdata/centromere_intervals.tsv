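chrom	start_mbp	end_mbp
1A	160	260
1B	180	280
1D	146	196
2A	270	370
2B	270	385
2D	220	300
3A	240	370
3B	280	390
3D	200	280
4A	245	360
4B	270	375
4D	194	226
5A	185	310
5B	145	240
5D	145	245
6A	240	355
6B	270	360
6D	184	230
7A	300	410
7B	250	315
7D	300	385
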