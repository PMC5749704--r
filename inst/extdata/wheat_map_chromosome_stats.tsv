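chromosome	n_markers	length_cM	unique_positions	non_redundant
1A	5294	147	423	120
2A	5870	107	290	93
3A	5019	156	343	121
4A	4933	181	294	119
5A	4194	193	423	138
6A	4025	127	237	87
7A	5311	176	424	131
1B	5523	133	375	106
2B	4283	131	307	85
3B	5811	164	412	127
4B	3489	113	262	104
5B	4748	178	361	124
6B	5932	113	298	95
7B	4456	126	316	104
1D	2091	158	225	124
2D	2468	151	235	119
3D	2436	200	333	173
4D	1507	149	311	164
5D	1710	220	324	190
6D	2464	185	256	132
7D	2157	198	320	160
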