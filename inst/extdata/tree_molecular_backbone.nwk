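(Sphenodon_punctatus,((((Amalosia_lesueurii,Strophurus_williamsi),Eublepharis_macularius),(Tarentola_annularis,(Chondrodactylus_turneri,Gehyra_variegata))),((Mabuya_sp,((Calyptommatus_sinebrachiatus,Nothobachia_ablephara),Zootoca_vivipara)),(((Python_sebae,((Thamnophis_sirtalis,Boaedon_fuliginosus),Vipera_aspis)),(Varanus_rosenbergi,(Varanus_indicus,Varanus_panoptes))),(((Iguana_iguana,Uta_stansburiana),((Anolis_sagrei,(Liolaemus_gravenhorsti,Liolaemus_tenuis)),Tropidurus_torquatus)),((Chamaeleo_calyptratus,Furcifer_lateralis),(Pogona_vitticeps,(Calotes_versicolor,Agama_impalearis))))))));
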