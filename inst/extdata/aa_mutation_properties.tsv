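aa	hydrophilicity	hydrophobicity	polarity	mass	sasa	polarizability
A	-0.5	1.8	8.1	71.08	129	0.046
R	3.0	-4.5	10.5	156.19	274	0.291
N	0.2	-3.5	11.6	114.10	195	0.134
D	3.0	-3.5	13.0	115.09	193	0.105
C	-1.0	2.5	5.5	103.14	167	0.128
Q	0.2	-3.5	10.5	128.13	225	0.180
E	3.0	-3.5	12.3	129.12	223	0.151
G	0.0	-0.4	9.0	57.05	104	0.000
H	-0.5	-3.2	10.4	137.14	224	0.230
I	-1.8	4.5	5.2	113.16	197	0.186
L	-1.8	3.8	4.9	113.16	201	0.186
K	3.0	-3.9	11.3	128.17	236	0.219
M	-1.3	1.9	5.7	131.19	224	0.221
F	-2.5	2.8	5.2	147.18	240	0.290
P	0.0	-1.6	8.0	97.12	159	0.131
S	0.3	-0.8	9.2	87.08	155	0.062
T	-0.4	-0.7	8.6	101.10	172	0.108
W	-3.4	-0.9	5.4	186.21	285	0.409
Y	-2.3	-1.3	6.2	163.18	263	0.298
V	-1.5	4.2	5.9	99.13	174	0.140
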