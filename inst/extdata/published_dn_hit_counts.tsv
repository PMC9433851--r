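mode	Temporal	Prefrontal	Parietal	Posterior cingulate
1	8	7	10	1
2	0	0	0	0
3	0	5	2	0
4	1	2	0	1
5	0	0	0	1
6	8	0	2	2
Total	17	14	14	5
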