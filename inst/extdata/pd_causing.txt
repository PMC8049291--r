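SNCA
PRKN
UCHL1
PARK7
LRRK2
PINK1
POLG
HTRA2
ATP13A2
FBXO7
GIGYF2
GBA
PLA2G6
EIF4G1
VPS35
DNAJC6
SYNJ1
DNAJC13
TMEM230
VPS13C
LRP10
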