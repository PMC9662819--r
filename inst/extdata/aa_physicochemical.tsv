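aa	molecular_weight	charge	hydrophobicity	aromaticity	hbond_potential	polarity	polarizability	flexibility
A	89.09	0	1.8	0	0	8.1	0.046	0.357
R	174.20	1	-4.5	0	5	10.5	0.291	0.529
N	132.12	0	-3.5	0	4	11.6	0.134	0.463
D	133.10	1	-3.5	0	4	13.0	0.105	0.511
C	121.15	0	2.5	0	1	5.5	0.128	0.346
Q	146.15	0	-3.5	0	4	10.5	0.180	0.493
E	147.13	1	-3.5	0	4	12.3	0.151	0.497
G	75.07	0	-0.4	0	0	9.0	0.000	0.544
H	155.16	0.1	-3.2	0.5	3	10.4	0.230	0.323
I	131.17	0	4.5	0	0	5.2	0.186	0.462
L	131.17	0	3.8	0	0	4.9	0.186	0.365
K	146.19	1	-3.9	0	3	11.3	0.219	0.466
M	149.21	0	1.9	0	1	5.7	0.221	0.295
F	165.19	0	2.8	1	0	5.2	0.290	0.314
P	115.13	0	-1.6	0	0	8.0	0.131	0.509
S	105.09	0	-0.8	0	2	9.2	0.062	0.507
T	119.12	0	-0.7	0	2	8.6	0.108	0.444
W	204.24	0	-0.9	1	1	5.4	0.409	0.305
Y	181.19	0	-1.3	1	2	6.2	0.298	0.420
V	117.15	0	4.2	0	0	5.9	0.140	0.386
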