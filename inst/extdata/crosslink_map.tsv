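label	chain1	res1	chain2	res2	cap	role
a5-b187	A	5	B	187	15	evidence
a606-b559	A	606	B	559	15	control
a672-p409	A	672	P	409	15	evidence
a673-b127	A	673	B	127	15	evidence
a685-b127	A	685	B	127	15	evidence
b615-p370	B	615	P	370	15	evidence
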