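residue	class
A	hydrophobic
V	hydrophobic
L	hydrophobic
I	hydrophobic
M	hydrophobic
F	hydrophobic
W	hydrophobic
C	hydrophobic
D	charged
E	charged
K	charged
R	charged
H	charged
G	turn
P	turn
S	turn
N	turn
T	hydrophilic
Q	hydrophilic
Y	hydrophilic
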