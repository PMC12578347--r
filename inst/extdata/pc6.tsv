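# PC6 per-residue physicochemical table: Kyte-Doolittle hydropathy,
# Hopp-Woods hydrophilicity, side-chain mass (Da), pK1 (alpha-COOH),
# pK2 (alpha-NH3+), isoelectric point. Columns are standardized at load.
residue	hydrophobicity	hydrophilicity	mass	pK1	pK2	pI
A	1.8	-0.5	15.03	2.34	9.69	6.00
C	2.5	-1.0	47.10	1.96	10.28	5.07
D	-3.5	3.0	59.04	1.88	9.60	2.77
E	-3.5	3.0	73.07	2.19	9.67	3.22
F	2.8	-2.5	91.13	1.83	9.13	5.48
G	-0.4	0.0	1.01	2.34	9.60	5.97
H	-3.2	-0.5	81.10	1.82	9.17	7.59
I	4.5	-1.8	57.11	2.36	9.68	6.02
K	-3.9	3.0	72.13	2.18	8.95	9.74
L	3.8	-1.8	57.11	2.36	9.60	5.98
M	1.9	-1.3	75.15	2.28	9.21	5.74
N	-3.5	0.2	58.06	2.02	8.80	5.41
P	-1.6	0.0	42.08	1.99	10.60	6.30
Q	-3.5	0.2	72.09	2.17	9.13	5.65
R	-4.5	3.0	100.14	2.17	9.04	10.76
S	-0.8	0.3	31.03	2.21	9.15	5.68
T	-0.7	-0.4	45.06	2.09	9.10	5.60
V	4.2	-1.5	43.09	2.32	9.62	5.96
W	-0.9	-3.4	130.17	2.83	9.39	5.89
Y	-1.3	-2.3	107.13	2.20	9.11	5.66
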