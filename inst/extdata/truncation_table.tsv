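codon	truncation_percent
UUI	49
AIA	7
UIU	6
IUA	5
IAA	5
UIC	5
CIC	4
ICA	3
AUI	3
AIU	3
CAI	3
IAU	3
ICC	3
IUC	3
CIU	3
ICU	2
IUU	2
IAC	1
AAI	0
CIA	0
AIC	0
IAI	84
ICI	64
UII	57
IUI	26
CII	8
IIA	7
AII	4
IIU	4
IIC	2
III	36
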