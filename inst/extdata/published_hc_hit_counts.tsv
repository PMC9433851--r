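mode	CA1	CA2/3	CA4	DG	HATA	Para	PrS	Sub	Fissure	Fimbria	ML	Tail
1	0	3	3	4	2	0	1	2	0	0	0	0
2	0	0	0	0	0	2	2	1	0	0	0	2
3	0	2	0	0	0	0	0	1	0	0	0	0
4	0	0	0	0	1	0	1	0	0	1	0	0
5	0	0	0	0	0	0	1	1	0	1	1	0
6	0	0	0	0	0	0	0	0	0	0	0	0
7	0	0	0	0	0	1	0	0	0	0	0	0
Total	0	5	3	4	3	3	4	5	0	2	1	2
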