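gene_id	chromosome	ploidy_D21	ploidy_T21	repeat_flag
g1	chr1	2	2	0
g2	chr21	2	3	0
g3	chr2	2	2	0
g4	chr22	2	2	1
g5	chr21	2	3	0
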