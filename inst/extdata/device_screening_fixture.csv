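"subject_id","wave","date","sedentary_min","light_min","moderate_min","vigorous_min","monitored_min","steps","sleep_min"
"S1",1,2021-01-10,1000,300,90,40,1430,8000,540
"S1",1,2021-01-11,1000,300,90,40,1430,8000,540
"S1",1,2021-01-12,1000,300,90,40,1430,8000,540
"S1",1,2021-01-13,1000,300,90,40,1430,8000,540
"S1",1,2021-01-14,1000,300,90,40,1430,8000,540
"S1",1,2021-01-15,1000,300,90,40,1430,8000,540
"S1",1,2021-01-16,1000,300,90,40,1430,8000,540
"S1",1,2021-01-17,1000,300,90,40,1430,8000,540
"S1",1,2021-01-18,1000,300,90,40,1430,8000,540
"S1",1,2021-01-19,1000,300,90,40,1430,8000,540
"S1",1,2021-01-20,1000,300,90,40,1430,8000,540
"S2",1,2021-01-10,1000,300,90,40,1430,8000,540
"S2",1,2021-01-11,1000,300,90,40,1430,8000,540
"S2",1,2021-01-12,1000,300,90,40,1430,8000,540
"S2",1,2021-01-13,800,250,70,32,1152,8000,540
"S2",1,2021-01-14,1256,100,30,14,1400,8000,540
"S2",1,2021-01-15,1000,300,90,40,1430,8000,540
"S2",1,2021-01-16,1000,300,90,40,1430,8000,540
"S2",1,2021-01-17,1000,300,90,40,1430,8000,540
"S2",1,2021-01-18,1000,300,90,40,1430,8000,540
"S2",1,2021-01-19,1000,300,90,40,1430,8000,540
"S2",1,2021-01-20,1000,300,90,40,1430,8000,540
"S3",1,2021-01-10,1000,300,90,40,1430,8000,540
"S3",1,2021-01-11,1000,300,90,40,1430,8000,540
"S3",1,2021-01-12,1000,300,90,40,1430,8000,540
"S3",1,2021-01-13,1000,300,90,40,1430,40000,540
"S3",1,2021-01-14,1000,300,90,40,1430,8000,100
"S3",1,2021-01-15,1000,300,90,40,1430,8000,540
"S3",1,2021-01-16,1000,300,90,40,1430,8000,540
"S3",1,2021-01-17,1000,300,90,40,1430,8000,540
"S3",1,2021-01-18,1000,300,90,40,1430,8000,540
"S3",1,2021-01-19,1000,300,90,40,1430,8000,540
"S3",1,2021-01-20,1000,300,90,40,1430,8000,540
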