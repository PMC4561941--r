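TP53
FGFR3
HRAS
TSC1
MDM2
RB1
ERCC2
NAT2
RAG1
MTCYB
ATM
TGFB1
ERBB3
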