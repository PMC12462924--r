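id	smiles
D1	CCCc1ccccc1
D2	C(=O)OCCC
D3	c1ccccc1C(=O)O
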