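species,optic_vesicle,otic_placode,limb_ridge,limb_aer,jaw_initiated,scale_anlagen
lizard_a,1,2,3,4,5,6
lizard_b,1,1,2,3,4,5
lizard_c,2,1,3,4,4,5
gecko_a,1,2,4,5,3,6
snake_a,1,2,-,-,3,4
snake_b,2,1,-,-,?,3
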