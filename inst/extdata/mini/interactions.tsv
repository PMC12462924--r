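drug_id	protein_id	label	affinity
D1	P1	1	7.6
D1	P2	0	5.2
D2	P2	1	7.2
D3	P1	0	5.6
D3	P2	1	7.2
D3	P3	0	5.6
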