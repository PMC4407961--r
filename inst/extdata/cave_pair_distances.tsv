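region	trait_set	row	distance	p_label	process
movile	body_size	extant	6.805	p<0.001	competition
movile	body_size	ancestral-lower	7.01	p<0.001	competition
movile	body_size	ancestral-mean	7.8	p<0.001	competition
movile	body_size	ancestral-upper	8.59	p<0.001	competition
frasassi	body_size	extant	3.775	p=0.365	random
frasassi	body_size	ancestral-lower	0.18	p=0.023	filtering
frasassi	body_size	ancestral-mean	0.25	p=0.031	filtering
frasassi	body_size	ancestral-upper	0.32	p=0.040	filtering
movile	channel	extant	2.8166	p=0.002	competition
movile	channel	ancestral-lower	0.9876	p=0.171	random
movile	channel	ancestral-mean	0.5494	p=0.024	filtering
movile	channel	ancestral-upper	0.4197	p=0.007	filtering
frasassi	channel	extant	3.386	p<0.0001	competition
frasassi	channel	ancestral-lower	2.63	p=0.07	random
frasassi	channel	ancestral-mean	2.69	p=0.056	random
frasassi	channel	ancestral-upper	2.704	p=0.055	random
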