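woman_id,exam_date,reader_id,reader_fellowship,reader_density,ai_density,age_years,bmi,fat_measure,thickness_mm
W001,2016-03-01,R01,1,b,b,52,27.1,0.41,55.2
W001,2017-03-06,R01,1,c,b,53,27.4,0.43,56.0
W001,2018-03-12,R02,0,x,b,54,27.2,0.42,55.5
W001,2019-03-18,R01,1,b,b,55,27.3,0.42,55.7
W002,2016-05-10,R02,0,a,a,61,31.0,0.62,64.1
W002,2017-05-15,R02,0,a,a,62,31.2,0.63,64.5
W002,2018-05-21,R02,0,b,a,63,31.1,0.62,64.2
W002,2019-05-27,R02,0,a,a,64,31.0,0.61,64.0
W003,2016-07-02,R03,1,d,d,45,22.5,0.28,41.3
W003,2017-07-08,R03,1,c,d,46,22.6,0.29,41.8
W003,2018-07-14,R03,1,d,d,47,22.4,0.27,41.1
W003,2019-07-20,R03,1,d,d,48,22.5,0.28,41.5
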