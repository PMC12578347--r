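# Reduced amino-acid index table: a representative subset of 11 widely used
# property scales from the public AAindex collection (hydropathy, Hopp-Woods
# hydrophilicity, Grantham polarity, isoelectric point, Grantham volume,
# Chou-Fasman helix and sheet propensities, net charge, average flexibility,
# bulkiness, relative mutability). The full collection holds hundreds of
# indices; the loader accepts any table of this layout, so a larger table can
# be plugged in. Columns are standardized at load.
residue	hydropathy	hydrophilicity	polarity	pI	volume	helix	sheet	charge	flexibility	bulkiness	mutability
A	1.8	-0.5	8.1	6.00	31	1.42	0.83	0	0.357	11.50	100
C	2.5	-1.0	5.5	5.05	55	0.70	1.19	0	0.346	13.46	20
D	-3.5	3.0	13.0	2.77	54	1.01	0.54	-1	0.511	11.68	106
E	-3.5	3.0	12.3	3.22	83	1.51	0.37	-1	0.497	13.57	102
F	2.8	-2.5	5.2	5.48	132	1.13	1.38	0	0.314	19.80	41
G	-0.4	0.0	9.0	5.97	3	0.57	0.75	0	0.544	3.40	49
H	-3.2	-0.5	10.4	7.59	96	1.00	0.87	0	0.323	13.69	66
I	4.5	-1.8	5.2	6.02	111	1.08	1.60	0	0.462	21.40	96
K	-3.9	3.0	11.3	9.74	119	1.16	0.74	1	0.466	15.71	56
L	3.8	-1.8	4.9	5.98	111	1.21	1.30	0	0.365	21.40	40
M	1.9	-1.3	5.7	5.74	105	1.45	1.05	0	0.295	16.25	94
N	-3.5	0.2	11.6	5.41	56	0.67	0.89	0	0.463	12.82	134
P	-1.6	0.0	8.0	6.30	32.5	0.57	0.55	0	0.509	17.43	56
Q	-3.5	0.2	10.5	5.65	85	1.11	1.10	0	0.493	14.45	93
R	-4.5	3.0	10.5	10.76	124	0.98	0.93	1	0.529	14.28	65
S	-0.8	0.3	9.2	5.68	32	0.77	0.75	0	0.507	9.47	120
T	-0.7	-0.4	8.6	5.66	61	0.83	1.19	0	0.444	15.77	97
V	4.2	-1.5	5.9	5.96	84	1.06	1.70	0	0.386	21.57	74
W	-0.9	-3.4	5.4	5.89	170	1.08	1.37	0	0.305	21.67	18
Y	-1.3	-2.3	6.2	5.66	136	0.69	1.47	0	0.420	18.03	41
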