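family,anatomy,n,class,levels,variables,task
Asterinidae,Body,885,Sex,2,20,binary
Drosophilidae,Wing,2926,Sex,2,96,binary
Emydidae,Shell,2161,Habitat,2,159,binary
Gasterosteidae,Skull,190,Habitat,2,210,binary
Gasterosteidae,Body,521,Sex,2,30,binary
Hominidae,Sacrum,101,Sex,2,300,binary
Hynobiidae/Cryptobranchidae,Palate,62,Habitat,2,48,binary
Muridae,Cranium,1251,Sex,2,2532,binary
Poeciliidae,Body,1449,Sex,2,26,binary
Serranidae/Sparidae,Body,259,Site,2,26,binary
Cichlidae,Jaw,1136,Tribe,14,126,multi
Colubridae+,Vertebrae,1260,Species,15,24,multi
Crocodylidae/Alligatoridae,Cranium,183,Species,8,234,multi
Drosophilidae,Wing,2926,Elevation,9,96,multi
Formicidae,Face,1494,Species,6,22,multi
Muridae,Cranium,1251,Genotype,26,2532,multi
Ocypodidae,Carapace,1867,Species,16,42,multi
Percidae,Body,423,Species,15,20,multi
Vespidae,Wing,206,Species,8,38,multi
Viviparidae,Shell,1224,Population,22,254,multi
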