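region,pct_men,pct_women
apex of nose,15.8,2.4
ala nasi L,26.3,29.3
ala nasi R,42.1,46.3
nasal bridge L,5.3,4.9
nasal bridge R,5.3,4.9
sulcus nasolabialis L,0,2.4
sulcus nasolabialis R,0,4.9
philtrum,0,0
vermilion border,26.3,9.8
vermilion,36.8,17.1
oral/labial commissure L,10.5,19.5
oral/labial commissure R,10.5,9.8
oral fissure,26.3,36.6
sulcus mentolabialis,5.3,7.3
zygomatic region,0,2.4
temporal region,15.8,41.5
frontal region,47.4,17.1
orbital region L,78.9,58.5
orbital region R,89.5,58.5
infraorbital region,0,4.9
mental region,21.1,9.8
parotid-masseteric region,26.3,12.2
buccal region,0,12.2
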