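taxid	name	rank	parent
1	root	no_rank	1
6656	Arthropoda	phylum	1
50557	Insecta	class	6656
7399	Hymenoptera	order	50557
7458	Apidae	family	7399
77572	Halictidae	family	7399
900010	Megachilidae	family	7399
900011	Andrenidae	family	7399
900021	Bombus	genus	7458
900022	Apis	genus	7458
81082	Melissodes	genus	7458
900023	Svastra	genus	7458
900024	Halictus	genus	77572
900025	Megachile	genus	900010
900026	Lasioglossum	genus	77572
900027	Agapostemon	genus	77572
900028	Andrena	genus	900011
900029	Triepeolus	genus	7458
900030	Augochloropsis	genus	77572
207634	Bombus griseocollis	species	900021
28643	Bombus pensylvanicus	species	900021
309941	Bombus affinis	species	900021
132113	Bombus impatiens	species	900021
239130	Bombus citrinus	species	900021
900101	Bombus auricomus	species	900021
900102	Bombus vagans	species	900021
900103	Bombus bimaculatus	species	900021
7460	Apis mellifera	species	900022
599269	Melissodes communis	species	81082
900104	Melissodes bimaculatus	species	81082
900105	Melissodes trinodis	species	81082
900109	Melissodes desponsus	species	81082
156364	Svastra obliqua	species	900023
77576	Halictus ligatus	species	900024
1452476	Megachile brevis	species	900025
586910	Megachile latimanus	species	900025
88517	Lasioglossum pectorale	species	900026
88495	Lasioglossum pilosum	species	900026
1038993	Lasioglossum albipenne	species	900026
1040006	Lasioglossum paradmirandum	species	900026
1479665	Agapostemon splendens	species	900027
205204	Andrena wilkella	species	900028
900106	Andrena rudbeckiae	species	900028
900107	Augochloropsis metallica	species	900030
900108	Augochloropsis metallica fulgida	subspecies	900107
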