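gene	partition	group
psbA	CBRY2, JPL, SMP, TW, CBTY2|CBTY1	ELSE
psaI	TW, CBTY2|JPL, CBRY2, CBTY1, SMP	ELSE
petL	TW, CBTY2|JPL, CBRY2, CBTY1, SMP	ELSE
chlN	CBTY1|TW, CBTY2, JPL, CBRY2, SMP	ELSE
psbD	JPL, SMP|TW, CBTY2, CBRY2, CBTY1	CZ
rpoA	JPL, SMP|TW, CBTY2, CBRY2, CBTY1	CZ
ycf2	CBRY2|JPL, SMP|CBTY2, CBTY1	CZ
cemA	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
rpl16	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
chlB	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
pafI	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
psbK	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
matK	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
rpl2	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
atpF	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
petB	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
rbcL	TW|JPL, CBTY2, CBRY2, CBTY1, SMP	TW
psbI	TW|JPL, CBTY2|CBRY2, CBTY1, SMP	TW2
petD	TW|JPL, CBTY2|CBRY2, CBTY1, SMP	TW2
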