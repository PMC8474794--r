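mouse	human
Figf/Vegfd	VEGFD
Figf	VEGFD
Wisp2/Ccn5	WISP2
Serpinh1/Hsp47	SERPINH1
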