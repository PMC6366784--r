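"port_id","name","lat","lon","ecoregion","ebsa","overlapping_species","biological_importance","hotspot"
"P01","Arrival port 1",73.3585791429505,-82.6920035951771,"ecoregion_6",1,1,1,1
"P02","Arrival port 2",71.7402120367624,-89.6761048152111,"ecoregion_1",1,1,0,0
"P03","Arrival port 3",59.0024683042429,-65.5614563673735,"ecoregion_8",1,0,0,0
"P04","Arrival port 4",56.1808428969234,-75.5689582391642,"ecoregion_7",0,0,1,0
"S01","Source port 1",53.8946842215955,-60.9560220621061,"source",0,0,0,0
"S02","Source port 2",46.5259418077767,-37.5663478965871,"source",0,0,0,0
"S03","Source port 3",50.1216047666967,-67.6197982334998,"source",0,0,0,0
"S04","Source port 4",51.2266040630639,-63.1219520848244,"source",0,0,0,0
"S05","Source port 5",42.5150806717575,-37.4104870208539,"source",0,0,0,0
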