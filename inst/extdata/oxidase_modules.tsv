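module_id	step_index	features
cytc_oxidase	1	coxA,ctaD
cytc_oxidase	2	coxB,ctaC
cytc_oxidase	3	coxC,ctaE
cbb3_oxidase	1	ccoN
cbb3_oxidase	2	ccoO
cbb3_oxidase	3	ccoP
bd_oxidase	1	cydA
bd_oxidase	2	cydB
bd_oxidase	3	cydX
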