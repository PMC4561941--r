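gene	km_rank	combo_rank
LRRK2	1	3
PARK7	2	7
PINK1	5	11
SNCA	8	14
GIGYF2	9	16
NR4A2	11	28
VPS35	12	24
PARK2	13	25
ATP13A2	20	40
GBA	24	39
UCHL1	NA	NA
PRKAG2	NA	NA
SNCB	NA	NA
PLA2G6	NA	NA
PDE8B	NA	NA
NDUFAF3	NA	NA
FOXRED1	NA	NA
NDUFA11	NA	NA
NDUFA1	NA	NA
NDUFAF2	NA	NA
NDUFAF4	NA	NA
NDUFAF5	NA	NA
NDUFAF6	NA	NA
NDUFS1	NA	NA
NDUFS2	NA	NA
NDUFS4	NA	NA
NUBPL	NA	NA
SLC6A3	NA	NA
DRD4	NA	NA
FGF20	NA	NA
SNCAIP	NA	NA
NDUFV2	NA	NA
STX1B	NA	NA
NDUFV1	NA	NA
HP	NA	NA
PARK	NA	NA
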