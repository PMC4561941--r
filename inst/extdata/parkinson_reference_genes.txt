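LRRK2
PARK7
PINK1
SNCA
GIGYF2
NR4A2
VPS35
PARK2
ATP13A2
GBA
UCHL1
PRKAG2
SNCB
PLA2G6
PDE8B
NDUFAF3
FOXRED1
NDUFA11
NDUFA1
NDUFAF2
NDUFAF4
NDUFAF5
NDUFAF6
NDUFS1
NDUFS2
NDUFS4
NUBPL
SLC6A3
DRD4
FGF20
SNCAIP
NDUFV2
STX1B
NDUFV1
HP
PARK
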