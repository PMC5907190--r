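# Small hypothetical Boolean metabolic network.
# Sources (no producing reaction): C1, C3, C6.  C2-R2-C7-R1 form a cycle.
compound	C1
compound	C2
compound	C3
compound	C4
compound	C5
compound	C6
compound	C7
compound	C8
compound	C9
enzyme	E1
enzyme	E2
reaction	R1	inputs=C1,C7	enzymes=E2	products=C2
reaction	R2	inputs=C2,C3	enzymes=E1	products=C4,C5,C7
reaction	R3	inputs=C6	enzymes=E1	products=C7,C8,C9
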