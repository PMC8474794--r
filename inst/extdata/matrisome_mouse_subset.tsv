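symbol	category
Gpc1	matrisome
Vcan	matrisome
Prss23	matrisome
Tnc	matrisome
Mmp3	matrisome
Adam12	matrisome
Col3a1	matrisome
Adamts18	matrisome
Plod2	matrisome
Postn	matrisome
Timp1	matrisome
Angpt2	matrisome
Col4a3	matrisome
Col5a2	matrisome
Sdc4	matrisome
Col18a1	matrisome
Igf1	matrisome
Slit2	matrisome
Adam10	matrisome
Egln1	matrisome
S100a4	matrisome
C1qc	matrisome
Mfap2	matrisome
Tnfref21	matrisome
Clec11a	matrisome
Adamts12	matrisome
Fgf10	matrisome
Fn1	matrisome
Ptn	matrisome
Leprel2	matrisome
Thbs1	matrisome
Tnfrsf1b	matrisome
Mfap5	matrisome
Col13a1	matrisome
Il15ra	matrisome
Adam23	matrisome
Ctsc	matrisome
Mdk	matrisome
Wisp1	matrisome
F10	matrisome
Serpina3g	matrisome
Sema6d	matrisome
Fgf21	matrisome
Wisp2	matrisome
Gas6	matrisome
Cxcl13	matrisome
Sfrp1	matrisome
Podn	matrisome
S100g	matrisome
Igfbp3	matrisome
Ngfr	matrisome
Omd	matrisome
Dhh	matrisome
Figf/Vegfd	matrisome
Bmp8a	matrisome
Plxnb2	matrisome
Spock2	matrisome
Tgfbi	matrisome
Col20a1	matrisome
Fbn1	matrisome
Tnfsf13b	matrisome
Htra3	matrisome
Vtn	matrisome
Ltbp1	matrisome
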