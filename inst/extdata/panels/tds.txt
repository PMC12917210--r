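TG
TPO
TSHR
PAX8
FOXE1
GLIS3
NKX2-1
SLC26A4
SLC5A5
SLC5A8
THRA
THRB
DIO1
DIO2
DUOX1
DUOX2
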