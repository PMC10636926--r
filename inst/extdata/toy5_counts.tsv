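gene_id	D21_rep1	D21_rep2	T21_rep1	T21_rep2
g1	10	30	12	28
g2	100	110	205	198
g3	0	0	0	0
g4	55	61	48	52
g5	500	480	760	740
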