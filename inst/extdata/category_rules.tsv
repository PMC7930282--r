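pattern	category	subcategory
kazal	Protease inhibitors	Kazal-type serine protease inhibitors
serpin|protease inhibitor|ovomucoid	Protease inhibitors	Serine protease inhibitors
cysteine-rich|kunitz|pacifastin	Protease inhibitors	Cysteine-rich proteins
trypsin|chymotrypsin|serine protease	Hydrolases	Serine proteases
metalloprote	Hydrolases	Metalloproteases
dipeptid	Hydrolases	Dipeptidases
aminopeptid	Hydrolases	Aminopeptidases
cathepsin|lysosomal .*protease	Hydrolases	Lysosomal proteases
carboxypeptid	Hydrolases	Carboxypeptidases
acid phosphatase	Hydrolases	Venom acid phosphatases
carboxylesterase|arylsulfatase	Hydrolases	Carboxylesterases
lipase	Hydrolases	Lipases
glucosidase	Hydrolases	Glucosidases
galactosidase	Hydrolases	Galactosidases
amylase	Hydrolases	Amylases
trehalase	Hydrolases	Trehalases
chitinase|chitotriosidase	Hydrolases	Chitinases
nuclease|ribonuclease|plancitoxin|endoribonuclease	Hydrolases	Nucleases
calreticulin	Immune related proteins	Calreticulin
calnexin	Immune related proteins	Calnexin
nucleobindin	Immune related proteins	Nucleobindin
c1q	Immune related proteins	C1q-like venom protein
odorant binding	Recognition/binding proteins	Odorant binding proteins
chemosensory	Recognition/binding proteins	Chemosensory proteins
lipoprotein receptor	Recognition/binding proteins	Low-density lipoprotein receptors
apolipoph|apolipoprotein	Recognition/binding proteins	Apolipophorins
insulin-like growth factor	Recognition/binding proteins	Insulin-like growth factor-binding protein
glutamyl cyclotransferase|glutathione	Glutathione metabolism	Glutathione metabolism
laccase	Oxidase	Laccase
dehydrogenase	Dehydrogenases	Alcohol dehydrogenase
isomerase|fk506	Isomerases	Isomerases
endoplasmin|heat shock	Heat shock proteins	Heat shock proteins
allergen	Other proteins	Allergens
royal jelly	Other proteins	Major royal jelly protein
adipocyte plasma membrane	Other proteins	Adipocyte plasma membrane-associated protein
ferritin	Other proteins	Ferritin
lachesin	Other proteins	Lachesin
astrocyte-derived neurotrophic	Other proteins	Mesencephalic astrocyte-derived neurotrophic factor
vitellogenin	Other proteins	Vitellogenin
agatoxin	Other proteins	Agatoxin
venom protein [a-z]\b	Unknown and hypothetical proteins	Named venom proteins
uncharacterized|hypothetical	Unknown and hypothetical proteins	Uncharacterized proteins
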