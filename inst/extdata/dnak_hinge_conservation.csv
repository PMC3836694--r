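label,residue,group,n,identity_pct,conservative_pct
I202,202,bacteria,1714,31,64
I202,202,animals,1388,5,90
I202,202,plants,597,5,83
S203,203,bacteria,1714,90,9
S203,203,animals,1388,92,7
S203,203,plants,597,86,10
E217,217,bacteria,1714,77,16
E217,217,animals,1388,87,9
E217,217,plants,597,79,12
A220,220,bacteria,1714,55,41
A220,220,animals,1388,48,51
A220,220,plants,597,59,39
T221,221,bacteria,1714,83,13
T221,221,animals,1388,94,4
T221,221,plants,597,88,5
N222,222,bacteria,1714,41,41
N222,222,animals,1388,14,11
N222,222,plants,597,17,22
G223,223,bacteria,1714,98,1
G223,223,animals,1388,91,1
G223,223,plants,597,83,1
D224,224,bacteria,1714,83,11
D224,224,animals,1388,94,4
D224,224,plants,597,91,5
T225,225,bacteria,1714,50,41
T225,225,animals,1388,89,2
T225,225,plants,597,82,3
H226,226,bacteria,1714,36,18
H226,226,animals,1388,83,4
H226,226,plants,597,82,4
L227,227,bacteria,1714,97,2
L227,227,animals,1388,96,3
L227,227,plants,597,92,7
G228,228,bacteria,1714,99,1
G228,228,animals,1388,99,0
G228,228,plants,597,98,1
G229,229,bacteria,1714,100,0
G229,229,animals,1388,99,0
G229,229,plants,597,99,1
E230,230,bacteria,1714,30,64
E230,230,animals,1388,87,8
E230,230,plants,597,68,27
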