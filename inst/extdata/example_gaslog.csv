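person_id,device_id,timestamp,ppm,flag
P01,D01,2019-06-03T08:00:00,0.0,
P01,D01,2019-06-03T08:00:15,0.0,
P01,D01,2019-06-03T08:00:30,1.6,
P01,D01,2019-06-03T08:00:45,0.0,
P01,D01,2019-06-03T10:15:00,6.2,
P01,D01,2019-06-03T10:15:15,11.4,
P01,D01,2019-06-03T10:15:30,3.0,
P01,D01,2019-06-03T10:15:45,0.0,
P02,D02,2019-06-03T08:00:00,0.0,
P02,D02,2019-06-03T13:40:00,29.0,ALARM
P02,D02,2019-06-03T16:00:00,0.0,
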