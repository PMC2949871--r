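residue	value
A	0.425
V	0.415
L	0.405
I	0.410
M	0.400
F	0.395
W	0.380
C	0.420
D	0.360
E	0.355
K	0.345
R	0.350
H	0.370
G	0.440
P	0.330
S	0.430
N	0.375
T	0.415
Q	0.365
Y	0.385
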