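kingdom	name	membership	phylum_or_group
virus	Anelloviridae	cancer_only	
virus	Astroviridae	cancer_only	
virus	Birnaviridae	cancer_only	
virus	Bornaviridae	cancer_only	
virus	Caliciviridae	cancer_only	
virus	Hepadnaviridae	cancer_only	
virus	Iridoviridae	cancer_only	
virus	Paramyxoviridae	cancer_only	
virus	Rhabdoviridae	cancer_only	
virus	Togaviridae	cancer_only	
virus	Nodaviridae	cancer_mc	
virus	Parvoviridae	cancer_mc	
virus	Arenaviridae	cancer_nc	
virus	Circoviridae	cancer_nc	
virus	Flaviviridae	cancer_nc	
virus	Orthomyxoviridae	cancer_nc	
virus	Papillomaviridae	cancer_nc	
virus	Adenoviridae	all_three	
virus	Bunyaviridae	all_three	
virus	Coronaviridae	all_three	
virus	Herpesviridae	all_three	
virus	Picornaviridae	all_three	
virus	Polyomaviridae	all_three	
virus	Poxviridae	all_three	
virus	Reoviridae	all_three	
virus	Retroviridae	all_three	
bacteria	Aeromonas	cancer_only	Proteobacteria
bacteria	Agrobacterium	cancer_only	Proteobacteria
bacteria	Anaplasma	cancer_only	Proteobacteria
bacteria	Arcobacter	cancer_only	Proteobacteria
bacteria	Bartonella	cancer_only	Proteobacteria
bacteria	Brucella	cancer_only	Proteobacteria
bacteria	Burkholderia	cancer_only	Proteobacteria
bacteria	Campylobacter	cancer_only	Proteobacteria
bacteria	Coxiella	cancer_only	Proteobacteria
bacteria	Francisella	cancer_only	Proteobacteria
bacteria	Helicobacter	cancer_only	Proteobacteria
bacteria	Klebsiella	cancer_only	Proteobacteria
bacteria	Legionella	cancer_only	Proteobacteria
bacteria	Methylobacterium	cancer_only	Proteobacteria
bacteria	Neisseria	cancer_only	Proteobacteria
bacteria	Orientia	cancer_only	Proteobacteria
bacteria	Pasteurella	cancer_only	Proteobacteria
bacteria	Proteus	cancer_only	Proteobacteria
bacteria	Pseudomonas	cancer_only	Proteobacteria
bacteria	Rickettsia	cancer_only	Proteobacteria
bacteria	Shewanella	cancer_only	Proteobacteria
bacteria	Shigella	cancer_only	Proteobacteria
bacteria	Sphingomonas	cancer_only	Proteobacteria
bacteria	Stenotrophomonas	cancer_only	Proteobacteria
bacteria	Vibrio	cancer_only	Proteobacteria
bacteria	Wolbachia	cancer_only	Proteobacteria
bacteria	Yersinia	cancer_only	Proteobacteria
bacteria	Abiotrophia	cancer_only	Firmicutes
bacteria	Bacillus	cancer_only	Firmicutes
bacteria	Enterococcus	cancer_only	Firmicutes
bacteria	Erysipelothrix	cancer_only	Firmicutes
bacteria	Geobacillus	cancer_only	Firmicutes
bacteria	Lactobacillus	cancer_only	Firmicutes
bacteria	Lactococcus	cancer_only	Firmicutes
bacteria	Listeria	cancer_only	Firmicutes
bacteria	Pediococcus	cancer_only	Firmicutes
bacteria	Peptoniphilus	cancer_only	Firmicutes
bacteria	Staphylococcus	cancer_only	Firmicutes
bacteria	Bacteroides	cancer_only	Bacteroidetes
bacteria	Flavobacterium	cancer_only	Bacteroidetes
bacteria	Porphyromonas	cancer_only	Bacteroidetes
bacteria	Prevotella	cancer_only	Bacteroidetes
bacteria	Corynebacterium	cancer_only	Actinobacteria
bacteria	Propionibacterium	cancer_only	Actinobacteria
bacteria	Chlamydia	cancer_only	Chlamydiae
bacteria	Chlamydophila	cancer_only	Chlamydiae
bacteria	Fusobacterium	cancer_only	Fusobacteria
bacteria	Streptobacillus	cancer_only	Fusobacteria
bacteria	Leptospira	cancer_only	Spirochaetes
bacteria	Treponema	cancer_only	Spirochaetes
bacteria	Mycoplasma	cancer_only	Tenericutes
bacteria	Ureaplasma	cancer_only	Tenericutes
bacteria	Morganella	mc_only	Proteobacteria
bacteria	Brevundimonas	nc_only	Proteobacteria
bacteria	Azorhizobium	cancer_mc	Proteobacteria
bacteria	Escherichia	cancer_mc	Proteobacteria
bacteria	Clostridium	cancer_mc	Firmicutes
bacteria	Bordetella	cancer_nc	Proteobacteria
bacteria	Salmonella	cancer_nc	Proteobacteria
bacteria	Chryseobacterium	cancer_nc	Bacteroidetes
bacteria	Mycobacterium	cancer_nc	Actinobacteria
bacteria	Streptococcus	cancer_nc	Firmicutes
fungus	Acremonium	cancer_only	
fungus	Ajellomyces	cancer_only	
fungus	Aspergillus	cancer_only	
fungus	Candida	cancer_only	
fungus	Cladosporium	cancer_only	
fungus	Coccidioides	cancer_only	
fungus	Cryptococcus	cancer_only	
fungus	Cunninghamella	cancer_only	
fungus	Issatchenkia	cancer_only	
fungus	Nosema	cancer_only	
fungus	Paracoccidioides	cancer_only	
fungus	Penicillium	cancer_only	
fungus	Pleistophora	cancer_only	
fungus	Pneumocystis	cancer_only	
fungus	Rhizomucor	cancer_only	
fungus	Rhizopus	cancer_only	
fungus	Rhodotorula	cancer_only	
fungus	Trichophyton	cancer_only	
fungus	Exophiala	mc_only	
fungus	Phialophora	mc_only	
fungus	Alternaria	cancer_mc	
fungus	Malassezia	cancer_mc	
fungus	Mucor	cancer_mc	
fungus	Trichosporon	cancer_mc	
fungus	Absidia	cancer_nc	
fungus	Cladophialophora	cancer_nc	
fungus	Fusarium	cancer_nc	
fungus	Geotrichum	all_three	
parasite	Ancylostoma	cancer_only	
parasite	Anisakis	cancer_only	
parasite	Armillifer	cancer_only	
parasite	Ascaris	cancer_only	
parasite	Babesia	cancer_only	
parasite	Balantidium	cancer_only	
parasite	Bipolaris	cancer_only	
parasite	Blastocystis	cancer_only	
parasite	Capillaria	cancer_only	
parasite	Dicrocoelium	cancer_only	
parasite	Dipylidium	cancer_only	
parasite	Echinococcus	cancer_only	
parasite	Echinostoma	cancer_only	
parasite	Entamoeba	cancer_only	
parasite	Enterobius	cancer_only	
parasite	Hartmannella	cancer_only	
parasite	Heteroconium	cancer_only	
parasite	Hymenolepis	cancer_only	
parasite	Leishmania	cancer_only	
parasite	Loa	cancer_only	
parasite	Metagonimus	cancer_only	
parasite	Necator	cancer_only	
parasite	Onchocerca	cancer_only	
parasite	Plasmodium	cancer_only	
parasite	Sarcocystis	cancer_only	
parasite	Schistosoma	cancer_only	
parasite	Strongyloides	cancer_only	
parasite	Toxascaris	cancer_only	
parasite	Toxocara	cancer_only	
parasite	Trichomonas	cancer_only	
parasite	Trichuris	cancer_only	
parasite	Wuchereria	cancer_only	
parasite	Prosthodendrium	mc_only	
parasite	Acanthamoeba	cancer_mc	
parasite	Naegleria	cancer_mc	
parasite	Taenia	cancer_mc	
parasite	Trichinella	cancer_mc	
parasite	Contracaecum	cancer_nc	
parasite	Diphyllobothrium	cancer_nc	
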