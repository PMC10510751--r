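# Loop initiation free energies by number of unpaired nucleotides
# (hairpin / bulge / internal), DNA defaults in kcal/mol at 37 C.
# Sizes beyond 10 are extended with the Jacobson-Stockmayer term
# dG(n) = dG(10) + 1.75 * R * T * ln(n / 10) in code. '.' = not applicable.
# size	hairpin	bulge	internal
1	.	4.0	.
2	.	2.9	4.1
3	3.5	3.1	3.2
4	3.5	3.2	3.6
5	3.3	3.3	4.0
6	4.0	3.5	4.4
7	4.2	3.7	4.6
8	4.3	3.9	4.8
9	4.5	4.1	4.9
10	4.6	4.3	4.9
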