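gene	hgvs_printed	hgvs_normalized	zygosity	sanger	agsa	agsa_percent	agsa_low_depth	seqnext	seqnext_percent	seqnext_low_depth
BRCA1	c.19-47del29	c.19_47del	het	1	1	56	1	0	NA	1
BRCA1	c.81-12delC	c.81-12del	het	0	0	NA	0	1	41	0
BRCA1	c.124delA	c.124del	het	1	1	48	0	1	48	0
BRCA1	c.212+1G>A	c.212+1G>A	het	1	1	72	1	0	NA	1
BRCA1	c.342-343delTC	c.342_343del	het	1	1	36	0	1	37	0
BRCA1	c.671-11dup	c.671-11dup	het	0	1	45	0	1	43	0
BRCA1	c.798-799del	c.798_799del	het	1	1	48	0	1	48	0
BRCA1	c.1116G>A	c.1116G>A	het	1	1	43	0	1	43	0
BRCA1	c.1390dupA	c.1390dup	het	1	1	49	0	1	48	0
BRCA1	c.1823-1826del	c.1823_1826del	het	1	1	46	0	1	46	0
BRCA1	c.1953_1956delGAAA	c.1953_1956del	het	1	1	35	0	1	34	0
BRCA1	c.2077G>A	c.2077G>A	het	1	1	60	0	1	62	0
BRCA1	c.2082C>T	c.2082C>T	hom	1	1	100	0	1	100	0
BRCA1	c.2269delG	c.2269del	het	1	1	66	0	1	66	0
BRCA1	c.2612C>T	c.2612C>T	het	1	1	42	0	1	42	0
BRCA1	c.3113A>G	c.3113A>G	het	1	1	51	0	1	52	0
BRCA1	c.3548A>G	c.3548A>G	het	1	1	49	0	1	49	0
BRCA1	3839-3843del5ins4	c.3839_3843delinsAGGC	het	1	1	52	0	1	52	0
BRCA1	c.4127del	c.4127del	het	1	1	56	0	1	44	0
BRCA1	c.4214-4215delIns5	NA	het	0	0	NA	0	1	23	0
BRCA1	c.4221delins9	NA	het	0	0	NA	0	1	26	0
BRCA1	C.4227-4237delins16	NA	het	0	0	NA	0	1	24	0
BRCA1	c.4243-4244delGA	c.4243_4244del	het	0	0	NA	0	1	26	0
BRCA1	c.4281_4282ins39	NA	het	1	1	44	0	0	NA	0
BRCA1	c.4308T>C	c.4308T>C	het	1	1	55	0	1	49	0
BRCA1	c.4575-4585del11	c.4575_4585del	het	1	1	46	0	1	43	0
BRCA1	c.4810C>T	c.4810C>T	het	1	1	58	0	1	53	0
BRCA1	c.5266dupC	c.5266dup	het	1	1	59	0	1	59	0
BRCA1	c.5333-20_5333-19insT	c.5333-20_5333-19insT	het	0	0	NA	0	1	25	0
BRCA2	c.37_44del8	c.37_44del	het	1	1	25	1	1	26	0
BRCA2	c.1114A>C	c.1114A>C	het	1	1	47	0	1	51	0
BRCA2	c.1246A>G	c.1246A>G	het	1	1	47	0	1	49	0
BRCA2	c.1553_1554insT	c.1553_1554insT	het	0	1	31	1	0	NA	1
BRCA2	c.1748_1749insA	c.1748_1749insA	het	0	1	47	1	1	26	0
BRCA2	c.1759-1761delinsC	NA	het	0	0	NA	0	1	25	0
BRCA2	c.1774delT	c.1774del	het	0	0	NA	0	1	33	0
BRCA2	c.1804-1806delins3	NA	het	0	0	NA	0	1	21	0
BRCA2	c.1803dupA	c.1803dup	het	0	0	NA	0	1	43	0
BRCA2	c.1815dupA	c.1815dup	het	0	1	68	0	1	31	0
BRCA2	c.1823dupA	c.1823dup	het	0	0	NA	0	1	33	0
BRCA2	c.1833dupA	c.1833dup	het	0	0	NA	0	1	21	0
BRCA2	c.2589T>A	c.2589T>A	het	0	0	NA	0	1	34	0
BRCA2	c.2803G>A	c.2803G>A	het	1	1	39	0	1	40	0
BRCA2	c.3479G>A	c.3479G>A	het	0	1	31	1	0	NA	0
BRCA2	c.3807T>C	c.3807T>C	het	1	1	44	0	1	42	0
BRCA2	c.4332-4333delTA	c.4332_4333del	het	0	0	NA	0	1	66	0
BRCA2	c.4350dupT	c.4350dup	het	0	0	NA	0	1	44	0
BRCA2	c.4781delins3	NA	het	0	0	NA	0	1	22	0
BRCA2	c.5073dupA	c.5073dup	het	1	1	42	0	1	41	0
BRCA2	c.5385dupA	c.5385dup	het	0	0	NA	0	1	22	0
BRCA2	c.5459_5460insA	c.5459_5460insA	het	0	1	32	1	0	NA	0
BRCA2	c.7977-10dup	c.7977-10dup	het	0	0	NA	0	1	70	0
BRCA2	c.8125dupA	c.8125dup	het	0	0	NA	0	1	23	0
BRCA2	c.8147-8148insA	c.8147_8148insA	het	0	0	NA	0	1	29	0
BRCA2	c.8574dup	c.8574dup	het	0	1	38	0	1	30	0
BRCA2	c.8797del	c.8797del	hom	0	1	NA	0	0	NA	0
BRCA2	c.8800del	c.8800del	het	0	1	80	1	0	NA	0
BRCA2	c.8823dupA	c.8823dup	het	0	0	NA	0	1	28	0
BRCA2	c.8946dup	c.8946dup	het	0	1	27	1	0	NA	0
BRCA2	c.10083del	c.10083del	het	0	0	NA	0	1	21	0
BRCA2	c.10115dupC	c.10115dup	het	0	0	NA	0	1	50	0
BRCA2	c.10122delC	c.10122del	het	0	0	NA	0	1	32	0
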