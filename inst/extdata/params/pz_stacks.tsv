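# P-Z stack nearest-neighbor free energy parameters at 37 C, with the
# analogous canonical stack obtained by replacing each P-Z pair with G-C
# (used for substitution statistics). stderr is the standard error of the
# regression. Units: kcal/mol.
# stack	dG37	stderr	gc_analog
AZ/TP	-1.44	0.17	AC/TG
TP/AZ	-1.45	0.15	TG/AC
TZ/AP	-1.49	0.15	TC/AG
PZ/ZP	-1.57	0.33	GC/CG
GZ/CP	-1.74	0.16	GC/CG
AP/TZ	-1.85	0.16	AG/TC
CZ/GP	-2.07	0.13	CC/GG
GP/CZ	-2.28	0.16	GG/CC
PP/ZZ	-2.35	0.13	GG/CC
CP/GZ	-2.77	0.16	CG/GC
ZP/PZ	-3.35	0.32	CG/GC
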