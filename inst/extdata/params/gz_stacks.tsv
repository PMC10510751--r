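# G-Z (wobble) stack nearest-neighbor free energy parameters at 37 C, with
# the analogous stack obtained by replacing each G-Z pair with A-T. stderr is
# the standard error of the regression (an underestimate: one experiment per
# parameter). Units: kcal/mol. No enthalpy/entropy values are fit for G-Z.
# stack	dG37	stderr	at_analog
GZ/ZG	1.70	0.48	AT/TA
GA/ZT	0.33	0.27	AA/TT
GG/ZZ	0.26	0.14	AA/TT
CZ/GG	-0.17	0.26	CT/GA
GP/ZZ	-0.50	0.28	AP/TZ
AG/TZ	-0.58	0.14	AA/TT
GG/CZ	-0.75	0.20	GA/CT
AZ/TG	-1.16	0.10	AT/TA
TG/AZ	-1.40	0.24	TA/AT
ZG/GZ	-1.67	0.41	TA/AT
CG/GZ	-1.79	0.26	CA/GT
GZ/ZP	-1.81	0.28	AZ/TP
ZP/GZ	-1.85	0.20	TP/AZ
GZ/CG	-2.07	0.17	GT/CA
PG/ZZ	-2.47	0.24	PA/ZT
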