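panel	gene	subgroup	product
qs_module_1	cqsA	autoinducer_synthase	CAI-1 ((S)-3-hydroxytridecan-4-one) synthase
qs_module_1	tdh	autoinducer_synthase	DPO (3,5-dimethyl-pyrazin-2-ol) production
qs_module_1	luxR	regulator	group-behaviour regulator
qs_module_2	lasI	autoinducer_synthase	3OC12-HSL synthase
qs_module_2	rhlI	autoinducer_synthase	C4-HSL synthase
qs_module_2	pqsH	autoinducer_synthase	PQS (2-heptyl-3-hydroxy-4-quinolone) synthase
qs_module_2	lasR	regulator	3OC12-HSL receptor
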