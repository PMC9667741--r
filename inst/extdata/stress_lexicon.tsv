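# Stress-category keyword lexicon: category<TAB>pattern
# Patterns match case-insensitively as fixed substrings of a gene product
# description; the first category in fixed order (metal, osmotic_drought,
# heat_cold, oxidative, acid_pH, dna_damage_uv, organic_pollutant) with any
# match wins. Seeded from curated product names of microbe-derived abiotic
# stress resistance genes reported in plant genomes.
metal	chromate
metal	copper
metal	magnesium
metal	cobalt transport
metal	ca2+-transporting
metal	phosphatase
metal	metal ion
metal	mercur
metal	arsen
metal	cadmium
metal	chra
metal	cutc
metal	copc
metal	mgta
osmotic_drought	symporter
osmotic_drought	sodium
osmotic_drought	potassium
osmotic_drought	chloride
osmotic_drought	choline dehydrogenase
osmotic_drought	sarcosine
osmotic_drought	na/k
osmotic_drought	zip family
osmotic_drought	trehalose
osmotic_drought	teichoic
osmotic_drought	cellulose synthase
osmotic_drought	dtdp
osmotic_drought	exopolysaccharide
osmotic_drought	malate synthase
osmotic_drought	isocitrate lyase
osmotic_drought	transaldolase
osmotic_drought	osmo
osmotic_drought	betaine
osmotic_drought	aquaporin
heat_cold	heat shock
heat_cold	heat-shock
heat_cold	cold-shock
heat_cold	cold shock
heat_cold	chaperon
heat_cold	dnaj
heat_cold	dnak
heat_cold	groel
heat_cold	hsp20
heat_cold	hsp60
heat_cold	hsp70
heat_cold	cspa
heat_cold	chitinase
heat_cold	protein hu
heat_cold	ribulose
heat_cold	carbonic anhydrase
heat_cold	photosystem
oxidative	peroxiredoxin
oxidative	peroxin
oxidative	haem peroxidase
oxidative	heme peroxidase
oxidative	glutathione
oxidative	glutaredoxin
oxidative	thioredoxin
oxidative	thiol-disulfide
oxidative	cysteine synthase
oxidative	glutamine synthetase
oxidative	glutamate synthase
oxidative	folylpolyglutamate
oxidative	methylase
oxidative	cytochrome-c oxidase
oxidative	cytochrome c oxidase
oxidative	cytochrome c reductase
oxidative	cytochrome synthesis
oxidative	ubiquinol
oxidative	menaquinol
oxidative	electron transfer flavoprotein
oxidative	phytoene
oxidative	isocitrate dehydrogenase
oxidative	thiamine
oxidative	seleno
oxidative	cobalamin
oxidative	cobw
oxidative	superoxide
oxidative	catalase
acid_pH	spermidine
acid_pH	putrescine
acid_pH	deiminase
acid_pH	proton extrusion
acid_pH	pcxa
acid_pH	carbamate kinase
acid_pH	polyamine
acid_pH	argininosuccinate
acid_pH	yhdg
acid_pH	acid resistance
acid_pH	ph homeostasis
dna_damage_uv	rad25
dna_damage_uv	rad51
dna_damage_uv	uvrd
dna_damage_uv	dna helicase
dna_damage_uv	dna repair
dna_damage_uv	excision repair
dna_damage_uv	photolyase
dna_damage_uv	recombinase
organic_pollutant	p450
organic_pollutant	laccase
organic_pollutant	lactamase
organic_pollutant	alkanesulfonate
organic_pollutant	monooxygenase
organic_pollutant	haloperoxidase
organic_pollutant	cbby
organic_pollutant	dioxygenase
organic_pollutant	multidrug
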