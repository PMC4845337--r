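motif_len	n_ssr	n_pal
2	35697	478
3	6905	5
4	549	1
5	32	0
6	23	0
7	5	0
8	15	0
9	26	0
10	17	0
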