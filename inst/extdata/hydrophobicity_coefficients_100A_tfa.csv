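residue,coefficient
A,1.11
C,0.04
D,-0.22
E,1.08
F,11.34
G,-0.35
H,-3.04
I,7.86
K,-3.53
L,9.44
M,6.57
N,-1.44
P,1.62
Q,-0.53
R,-2.58
S,-0.33
T,0.48
V,4.86
W,13.12
Y,5.40
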