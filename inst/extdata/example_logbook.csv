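person_id,date,workplace,category,start,duration_or_end,flushing,manhole_entry,comment
P01,2019-06-03,water_network,driving,07:00,60,none,0,
P01,2019-06-03,water_network,manhole_entry,10:00,1030,none,1,valve check
P02,2019-06-03,wastewater_network,sewer_maintenance,08:00,120,some,0,
P02,2019-06-03,wastewater_network,driving,13:00,45,none,0,
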