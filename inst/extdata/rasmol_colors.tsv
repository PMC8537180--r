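residue	color
D	#E60A0A
E	#E60A0A
C	#E6E600
M	#E6E600
K	#145AFF
R	#145AFF
S	#FA9600
T	#FA9600
F	#3232AA
Y	#3232AA
N	#00DCDC
Q	#00DCDC
G	#EBEBEB
L	#0F820F
V	#0F820F
I	#0F820F
A	#C8C8C8
W	#B45AB4
H	#8282D2
P	#DC9682
X	#BEBEBE
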