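id,sex,calf,role,period,locs,start,end,date50s,m_time,td,ice08_pct,ice10_pct
2003-24642,F,TRUE,Mo,1,504,2003-12-28,2004-05-18,2004-02-02,36,142,59.1,61.5
2005-10946,F,TRUE,Mo,1,132,2005-10-25,2006-01-03,2005-12-02,38,70,17.4,34.1
2005-24641,F,TRUE,Mo,1,159,2005-10-27,2006-02-08,2005-12-26,60,104,10.7,11.3
2009-87783,F,TRUE,Mo,1,577,2009-10-19,2010-02-03,2009-12-29,71,107,21.8,0.0
2009-87771,U,FALSE,Ad,1,362,2009-09-21,2009-11-13,2009-10-19,28,53,35.6,13.5
2012-111871,F,TRUE,Mo,1,2385,2012-11-25,2013-04-20,2013-01-02,38,146,52.8,73.9
2012-121189,M,FALSE,Ad,1,1546,2012-10-25,2013-07-26,2012-12-14,50,274,61.3,61.1
2012-87632,F,TRUE,Mo,1,1335,2013-01-20,2013-04-13,NA,NA,83,100.0,100.0
2017-172000,U,FALSE,Ad,2,781,2017-12-07,2018-01-21,2018-01-03,27,45,0.0,0.0
2017-172002,F,TRUE,Mo,2,1763,2017-11-16,2018-03-11,2017-12-21,35,115,7.1,5.0
2017-84484,M,FALSE,Es,2,704,2017-12-05,2018-01-14,2018-01-07,33,40,0.0,0.0
2017-111870,M,FALSE,Un,2,1849,2017-11-03,2018-02-07,2017-12-01,28,96,0.0,0.0
2017-172001,F,TRUE,Mo,2,2226,2017-11-28,2018-03-17,2017-12-26,28,109,45.0,29.2
2017-121203,M,FALSE,Es,2,2051,2017-10-26,2018-02-05,2017-11-22,27,102,21.2,19.3
2017-120937,M,FALSE,Es,2,1733,2017-10-30,2018-01-19,2017-11-24,25,81,0.0,0.0
2018-84485,F,TRUE,Mo,2,810,2018-12-04,2019-01-24,2019-01-04,31,51,0.0,0.0
2018-112696,F,TRUE,Mo,2,700,2018-10-26,2018-12-06,2018-11-29,34,41,0.0,0.0
2018-172008,M,FALSE,Es,2,2252,2018-10-22,2019-02-06,2018-11-26,35,107,67.2,69.5
2018-121191,F,TRUE,Mo,2,894,2018-11-29,2019-01-17,2019-01-09,41,49,0.0,0.0
2018-171994,M,FALSE,Es,2,1291,2018-10-25,2018-12-22,2018-11-30,36,58,0.0,0.0
2019-194591,U,FALSE,Ad,2,1204,2019-10-27,2020-01-10,2019-12-16,50,75,0.0,0.0
2019-194601,F,TRUE,Mo,2,402,2019-10-24,2019-12-10,2019-12-01,38,47,0.0,0.0
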