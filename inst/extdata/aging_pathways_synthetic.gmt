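Valine, Leucine and Isoleucine Degradation	synthetic BCAA catabolism set	valine	leucine	isoleucine	3-hydroxyisobutyrate	3-methyl-2-oxovalerate	ketoleucine
Urea Cycle	synthetic urea cycle set	aspartate	ornithine	arginine	citrulline	urea	fumarate
Ammonia Recycling	synthetic ammonia recycling set	asparagine	aspartate	glutamine	glutamate	ammonia
Glycolysis and Gluconeogenesis	synthetic glycolysis set	glucose	pyruvate	lactate	glucose-6-phosphate	fructose-6-phosphate	phosphoenolpyruvate
Tryptophan Metabolism	synthetic tryptophan set	tryptophan	kynurenine	serotonin	melatonin	indole-3-acetate
Citric Acid Cycle	synthetic TCA set	citrate	isocitrate	alpha-ketoglutarate	succinate	fumarate	malate	oxaloacetate
Cholesterol Biosynthesis	synthetic cholesterol set	total_cholesterol	lanosterol	squalene	mevalonate	7-dehydrocholesterol	desmosterol
Triacylglycerol Metabolism	synthetic TAG set	triacylglyceride	glycerol	glycerol-3-phosphate	palmitate	oleate
Glutathione Metabolism	synthetic glutathione set	glutathione	glycine	cysteine	glutamate	pyroglutamate
Purine Metabolism	synthetic purine set	uric_acid	hypoxanthine	xanthine	inosine	adenine	guanine
Ketone Body Metabolism	synthetic ketone set	acetoacetate	3-hydroxybutyrate	acetone
Alanine Metabolism	synthetic alanine set	alanine	pyruvate	glutamate
Betaine Metabolism	synthetic betaine set	betaine	choline	dimethylglycine	sarcosine	methionine
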