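species,ecv_cm3,group_size,neocortex_ratio,life_expectancy
ring_tailed_lemur,25,16,1.2,25
lion_tailed_macaque,85,18,2.1,27
rhesus_macaque,90,40,2.2,30
sooty_mangabey,100,35,2.3,27
orangutan,380,5,3.0,45
chimpanzee,390,45,3.2,45
western_gorilla,490,10,2.7,40
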