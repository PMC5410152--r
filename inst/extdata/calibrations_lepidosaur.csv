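clade,tips,age_ma,note
Sauria,Sphenodon_punctatus;Iguana_iguana,256,root of the lepidosaur tree
Rhynchocephalia,Sphenodon_punctatus,238,single sampled tip; stem calibration unused
Iguania,Iguana_iguana;Agama_impalearis,105,99 + 3 + 3
Acrodonta,Chamaeleo_calyptratus;Agama_impalearis,102,99 + 3
Chamaeleonidae,Chamaeleo_calyptratus;Furcifer_lateralis,99,
Agamidae,Pogona_vitticeps;Agama_impalearis,99,
Chamaeleo,Chamaeleo_calyptratus,13,single sampled tip
Tropiduridae,Tropidurus_torquatus,15,single sampled tip
Iguanidae,Iguana_iguana,56,single sampled tip
Anolis,Anolis_sagrei,20,single sampled tip
Gekkota,Amalosia_lesueurii;Gehyra_variegata,150,
Gekkonidae,Chondrodactylus_turneri;Gehyra_variegata,15,
Diplodactylidae,Amalosia_lesueurii;Strophurus_williamsi,20,
Serpentes,Python_sebae;Vipera_aspis,167,
Pythonidae,Python_sebae,35,single sampled tip
Colubridae,Thamnophis_sirtalis,31,single sampled tip
Lamprophiidae,Boaedon_fuliginosus,17,single sampled tip
Viperidae,Vipera_aspis,20,single sampled tip
Anguimorpha,Varanus_rosenbergi;Varanus_panoptes,145,varanids only in the sample
Lacertiformes,Calyptommatus_sinebrachiatus;Zootoca_vivipara,99,
Gymnophthalmidae,Calyptommatus_sinebrachiatus;Nothobachia_ablephara,66,dated by oldest teiid
Scincoidea,Mabuya_sp,150,single sampled tip
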