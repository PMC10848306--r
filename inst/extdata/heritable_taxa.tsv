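# Reference registry of the 32 species-level heritable rumen bacteria.
# source_name repeats where the published list repeats a name; taxon_id
# disambiguates repeats by order of appearance with "_1" suffixes.
taxon_id	source_name
p-251-o5	p-251-o5
Family_XIII_AD3011_group	Family_XIII_AD3011_group
Pirellula	Pirellula
Izemoplasmatales	Izemoplasmatales
Rikenellaceae	Rikenellaceae
Ruminococcaceae	Ruminococcaceae
Monoglobus	Monoglobus
Defluviitaleaceae_UCG-011	Defluviitaleaceae_UCG-011
[Eubacterium]_hallii_group	[Eubacterium]_hallii_group
Anaerovoracaceae	Anaerovoracaceae
Treponema	Treponema
Christensenellaceae	Christensenellaceae
Izemoplasmatales_1	Izemoplasmatales
Lachnospiraceae	Lachnospiraceae
Family_XIII_AD3011_group_1	Family_XIII_AD3011_group
Selenomonas_bovis	Selenomonas_bovis
Atopobium	Atopobium
Pseudoscardovia	Pseudoscardovia
wallaby_gut	wallaby_gut
UCG-002	UCG-002
Lachnospiraceae_NK4B4_group	Lachnospiraceae_NK4B4_group
Lachnospiraceae_XPB1014_group	Lachnospiraceae_XPB1014_group
Clostridia_UCG-014	Clostridia_UCG-014
Roseburia	Roseburia
uncultured_prokaryote	uncultured_prokaryote
uncultured_Lachnospiraceae	uncultured_Lachnospiraceae
Bacteroidetes_BD2-2	Bacteroidetes_BD2-2
[Eubacterium]_hallii_group_1	[Eubacterium]_hallii_group
Eubacterium_sp.	Eubacterium_sp.
Flexilinea	Flexilinea
Roseburia_1	Roseburia
Enterorhabdus_sp.	Enterorhabdus_sp.
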