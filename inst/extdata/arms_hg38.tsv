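chrom	arm	start	end
1	p	1	121700000
1	q	125100001	248956422
2	p	1	91800000
2	q	96000001	242193529
3	p	1	87800000
3	q	94000001	198295559
4	p	1	48200000
4	q	51800001	190214555
5	p	1	46100000
5	q	50600001	181538259
6	p	1	58500000
6	q	62600001	170805979
7	p	1	58100000
7	q	62100001	159345973
8	p	1	43200000
8	q	47200001	145138636
9	p	1	42200000
9	q	45500001	138394717
10	p	1	38000000
10	q	41600001	133797422
11	p	1	51000000
11	q	55800001	135086622
12	p	1	33200000
12	q	37800001	133275309
13	p	1	16500000
13	q	18900001	114364328
14	p	1	16100000
14	q	18200001	107043718
15	p	1	17500000
15	q	20500001	101991189
16	p	1	35300000
16	q	38400001	90338345
17	p	1	22700000
17	q	27400001	83257441
18	p	1	15400000
18	q	21500001	80373285
19	p	1	24200000
19	q	28100001	58617616
20	p	1	25700000
20	q	30400001	64444167
21	p	1	10900000
21	q	13000001	46709983
22	p	1	13700000
22	q	17400001	50818468
X	p	1	58100000
X	q	63800001	156040895
Y	p	1	10300000
Y	q	10600001	57227415
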