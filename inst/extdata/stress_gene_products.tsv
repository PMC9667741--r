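# Curated product descriptions of microbe-derived abiotic stress resistance
# genes reported across fourteen plant genomes, with their published stress
# category: product<TAB>category. Used as an in-package fixture for the
# category lexicon.
Magnesium-translocating P-type ATPase MgtA	metal
Magnesium and cobalt transport protein	metal
Copper homeostasis protein CutC	metal
Copper resistance protein CopC	metal
Chromate transporter ChrA	metal
Copper-transporting ATPase	metal
P-type copper ATPase	metal
Ca2+-transporting atpase	metal
Acid phosphatase	metal
Stromal 70 kDa chaperone protein DnaK	heat_cold
DnaJ-class molecular chaperone with C-terminal Zn finger domain	heat_cold
DNA-binding protein HU	heat_cold
Chaperonin GroEL (HSP60 family)	heat_cold
Small heat shock protein (HSP20) family	heat_cold
DnaJ molecular chaperone homology domain	heat_cold
Heat shock protein 70	heat_cold
Heat shock protein 70KD	heat_cold
Heat shock protein. Metallo peptidase. MEROPS family M48B	heat_cold
Heat shock factor binding protein 1	heat_cold
Chaperone clpb, heat shock protein	heat_cold
Molecular chaperone	heat_cold
Cold-shock DNA-binding protein CspA	heat_cold
Chitinase	heat_cold
Chitinase family 18 (EC:3.2.1.14)	heat_cold
Ribulose 1,5-bisphosphate carboxylase large subunit (EC 4.1.1.39)	heat_cold
Mitochondrial carbonic anhydrase, beta type	heat_cold
Photosystem II protein VI	heat_cold
Photosystem II cytochrome b6/f complex subunit V	heat_cold
Spermidine/putrescine transporter	acid_pH
Arginine deiminase ArcA (EC 3.5.3.6)	acid_pH
Proton extrusion protein PcxA	acid_pH
Carbamate kinase (EC 2.7.2.2)	acid_pH
Polyamine transporter 3	acid_pH
Basic amino acid/polyamine antiporter, APA family/solute carrier family 7 (L-type amino acid transporter), member 9	acid_pH
Argininosuccinate lyase	acid_pH
Spermidine/putrescine transport system	acid_pH
Argininosuccinate synthase (EC 6.3.4.5)	acid_pH
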