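ASSOCIATED_WITH	90000
PART_OF	45000
COEXISTS_WITH	30000
AFFECTS	22500
PREDISPOSES	18000
CAUSES	15000
TREATS	12857
INTERACTS_WITH	11250
LOCATION_OF	10000
ISA	9000
DISRUPTS	8182
STIMULATES	7500
INHIBITS	6923
PROCESS_OF	6429
USES	6000
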