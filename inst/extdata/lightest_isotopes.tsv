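symbol	isotope	mass
H	1H	1.007825032
C	12C	12.000000000
N	14N	14.003074004
O	16O	15.994914620
F	19F	18.998403163
Na	23Na	22.989769282
Si	28Si	27.976926535
P	31P	30.973761998
S	32S	31.972071174
Cl	35Cl	34.968852682
K	39K	38.963706487
Br	79Br	78.918337576
I	127I	126.904471853
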