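gene_symbol	weight	class
WISP2	-3.31	driver
CXCL13	-2.7	driver
POSTN	1.785	driver
COL5A2	2.29	driver
COL13A1	2.21	driver
COL18A1	2.71	driver
OMD	-1.93	driver
CLEC11A	1.17	driver
FBN1	-2.63	driver
SFRP1	-2.21	driver
SPOCK2	-1.74	driver
VCAN	3.1	suppressor
TIMP1	1.75	suppressor
IGF1	1.43	suppressor
SLIT2	2.02	suppressor
TGFBI	-1.73	suppressor
CTSC	1.94	suppressor
VTN	-1.48	suppressor
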