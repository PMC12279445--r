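pair	gene_flow	allopatric	recurrent	balancing	total_windows
WCC1|WCC2	1	242	513	57	3969
EC|WCC2	1	234	533	61	4103
CM|EC	5	214	523	49	3971
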