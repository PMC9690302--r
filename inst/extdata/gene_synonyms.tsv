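alias	canonical
ycf3	pafI
ycf4	pafII
ycf10	cemA
ycf5	ccsA
ycf9	psbZ
ycf6	petN
orf168	ycf2
psbN	pbf1
rpl22	rpl22
infA	infA
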