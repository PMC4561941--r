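SE|23867826||ab|4|text|miRNA expression arrays and individual qPCR were used to identify and confirm miRNAs that were downregulated in malignant urothelial cells
SE|23867826||ab|4|entity|C1101610|MicroRNAs|bacs,nnon|bacs|||miRNAs||||1000|972|978
SE|23867826||ab|4|relation|3|1|C1101610|MicroRNAs|bacs,nnon|bacs|||miRNAs||||1000|972|978|VERB|DISRUPTS||995|1008|5|1|C0227599|Transitional epithelial cell of urinary bladder|cell|cell|||urothelial cells||||890|1022|1038
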