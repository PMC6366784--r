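"vessel_id","pathway","arrival_port","discharge_date","last_port_of_call","volume_on_board_mt","tank_id","source_port","uptake_date","tank_volume_mt","source_salinity_ppt","exchange_type","exchange_location"
"D001","domestic","P02","2006-08-05","S03",8601.3,"T1",,,1159.7,28.3,"none",
"D001","domestic","P02","2006-08-05","S03",8601.3,"T2",,,5653.3,31.6,"none",
"D001","domestic","P02","2006-08-05","S03",8601.3,"T3",,,1378.7,9.2,"none",
"D002","domestic","P01","2014-05-13","S02",19968,"T1","S02",,2373.4,6.6,,
"D002","domestic","P01","2014-05-13","S02",19968,"T2","S02",,1313.4,0.1,,
"D002","domestic","P01","2014-05-13","S02",19968,"T3","S02",,15330.3,23.7,,
"D003","domestic","P03","2005-09-05","S04",3882.7,"T1",,,3697.8,3.4,"none",
"D004","domestic","P01","2012-08-20","S04",2600.8,"T1",,,2477,30.7,"none",
"D005","domestic","P01","2011-06-02","S02",14369.1,"T1","S04",,11382.5,30.8,,
"D005","domestic","P01","2011-06-02","S02",14369.1,"T2","S02",,2302.4,10.6,,
"D006","domestic","P03","2008-06-28","S05",3216.5,"T1","S05",,424.8,31.6,"none",
"D006","domestic","P03","2008-06-28","S05",3216.5,"T2","S03",,2638.5,15.7,"none",
"I001","international","P04","2014-09-17","S01",984.9,"T1","S01","2014-06-14",,19.9,"mid_ocean",
"I003","international","P01","2010-04-27","S04",1852.3,"T1",,"2010-01-13",364.3,32.7,"mid_ocean",
"I003","international","P01","2010-04-27","S04",1852.3,"T2",,"2009-12-24",1175.2,11.2,"mid_ocean",
"I003","international","P01","2010-04-27","S04",1852.3,"T3",,"2010-03-01",224.6,29.3,"mid_ocean",
"I006","international","P01","2005-08-20","S01",13171.6,"T1",,"2005-07-23",1227.1,0.5,"mid_ocean",
"I006","international","P01","2005-08-20","S01",13171.6,"T2",,"2005-04-15",9039.3,12.8,"mid_ocean",
"I006","international","P01","2005-08-20","S01",13171.6,"T3",,"2005-05-16",2278,26.6,"mid_ocean",
"I008","international","P01","2009-08-17","S02",16264.7,"T1","S02",,,6.4,"mid_ocean",
"I008","international","P01","2009-08-17","S02",16264.7,"T2","S02",,,0.5,"mid_ocean",
"I008","international","P01","2009-08-17","S02",16264.7,"T3","S02",,,27.6,"mid_ocean",
"I002","international","P01","2013-07-27","S05",,,,,,,,
"I004","international","P01","2009-07-20","S01",,,,,,,,
"I005","international","P02","2014-08-04","S01",,,,,,,,
"I007","international","P03","2005-06-11","S04",,,,,,,,
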