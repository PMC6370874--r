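# demo cancer-gene list (one symbol per line)
HRAS
KRAS
TP53
EGFR
CTNNB1
BRAF
NRAS
SMO
PTEN
SMAD4
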