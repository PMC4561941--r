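gene	km_rank	combo_rank
TP53	1	1
FGFR3	2	2
HRAS	6	7
TSC1	23	26
MDM2	29	32
RB1	58	70
ERCC2	70	82
NAT2	75	87
RAG1	NA	NA
MTCYB	NA	NA
ATM	NA	NA
TGFB1	NA	NA
ERBB3	NA	NA
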