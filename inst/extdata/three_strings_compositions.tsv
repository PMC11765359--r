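#n=6
#h=3
1	0	1
1	1	5
2	1	4
2	2	2
3	2	6
4	2	2
4	3	4
5	3	5
5	4	1
6	4	6
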