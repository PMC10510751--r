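# Global duplex penalties (unified DNA set). Units: dG37/dH kcal/mol,
# dS cal/(mol*K). terminal_PZ is 0 by the end-penalty regression finding;
# terminal_GZ defaults to 0 (no end correction, as for G-U and m6A-U).
# term	dG37	dH	dS
intermolecular_initiation	1.96	0.2	-5.7
terminal_AT	0.05	2.2	6.9
symmetry_correction	0.43	0.0	-1.4
terminal_PZ	0.00	0.0	0.0
terminal_GZ	0.00	0.0	0.0
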