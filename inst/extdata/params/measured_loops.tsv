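# Measured loop increments for the expanded alphabet (main-text values only;
# supplementary measurements can be supplied as an overlay file of the same
# dialect). Units: kcal/mol.
# type: tmm = terminal mismatch on closing pair; d5/d3 = dangling end.
# closing written as the helix-end pair X-Y (top-bottom); content is the
# mismatch pair a-b or the dangling base.
# type	closing	content	dG37
tmm	T-A	Z-Z	-0.91
tmm	G-C	Z-Z	-0.76
tmm	T-A	P-P	-0.51
d5	A-T	Z	-0.80
d5	C-G	P	-0.37
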