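chromosome	ISBP-derived	intergenic	exonic	intronic
1A	60774	131481	5851	9367
2A	75889	153026	7058	11423
3A	40179	98901	4433	7028
4A	36467	90892	4464	6241
5A	56534	118432	4493	8575
6A	54744	113872	6429	9272
7A	65875	159995	5757	9953
1B	59926	136537	5517	9600
2B	81977	168903	9864	14169
3B	96264	213332	8219	13499
4B	32557	62266	3055	4920
5B	75310	163224	8627	13169
6B	58675	136036	5071	8371
7B	65255	141547	3913	7479
1D	15977	38373	2271	2874
2D	17933	38924	2737	4257
3D	9846	23035	921	1280
4D	8893	14271	511	620
5D	12343	26679	1639	2079
6D	11065	26582	1664	2072
7D	16819	37514	1708	2273
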