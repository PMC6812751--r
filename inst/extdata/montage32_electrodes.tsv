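label	x	y
Fp1	-0.29	0.90
Fpz	0.00	0.95
Fp2	0.29	0.90
F7	-0.77	0.56
F3	-0.34	0.47
Fz	0.00	0.48
F4	0.34	0.47
F8	0.77	0.56
FC5	-0.59	0.27
FC1	-0.20	0.24
FC2	0.20	0.24
FC6	0.59	0.27
T7	-0.95	0.00
C3	-0.48	0.00
Cz	0.00	0.00
C4	0.48	0.00
T8	0.95	0.00
TP9	-0.93	-0.30
CP5	-0.59	-0.27
CP1	-0.20	-0.24
CP2	0.20	-0.24
CP6	0.59	-0.27
TP10	0.93	-0.30
P7	-0.77	-0.56
P3	-0.34	-0.47
Pz	0.00	-0.48
P4	0.34	-0.47
P8	0.77	-0.56
POz	0.00	-0.72
O1	-0.29	-0.90
Oz	0.00	-0.95
O2	0.29	-0.90
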