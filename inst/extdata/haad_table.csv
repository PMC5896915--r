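date,WK,RA,NAdm,WS,WD,EW,NS,PR,TM,RH,TS,GR,NG,GR_lg,NG_lg,O3,PM25
1993-02-14,Su,69,2.3,28,360,0.0,-28.0,0.0,27,37,Y,NA,NA,NA,NA,NA,NA
1993-02-15,Mo,70,2.3,59,350,10.2,-58.1,0.8,24,47,N,NA,NA,NA,NA,NA,NA
1994-11-20,Su,52,1.7,26,310,19.9,-16.7,3.6,23,33,N,107,336,73,126,NA,NA
1996-11-03,Su,52,1.7,37,360,0.0,-37.0,2.5,19,73,Y,251,281,102,258,NA,NA
2001-02-18,Su,54,1.7,42,10,-7.3,-41.4,0.0,29,28,N,NA,NA,NA,NA,NA,NA
2001-11-25,Su,53,1.6,31,340,10.6,-29.1,1.2,20,38,N,48,151,76,227,NA,NA
2003-11-20,Th,76,2.3,22,350,3.8,-21.7,4.4,30,45,Y,60,761,91,820,24,9
2005-02-21,Mo,47,1.4,13,250,12.2,4.4,0.0,22,67,N,NA,NA,NA,NA,11,8
2009-02-16,Mo,52,1.4,9,70,-8.5,-3.1,0.0,24,44,N,NA,NA,NA,NA,17,22
2009-10-31,Sa,58,1.5,26,10,-4.5,-25.6,9.4,29,39,Y,105,126,31,84,25,5
2009-11-01,Su,49,1.3,2,90,-2.0,0.0,1.6,16,90,N,22,44,59,100,18,5
2010-11-13,Sa,71,1.8,21,180,0.0,21.0,19.8,14,94,N,24,130,147,492,14,NA
2010-11-25,Th,144,3.7,24,220,15.4,18.4,23.0,19,92,N,23,109,92,675,11,3
2011-10-29,Sa,65,1.7,22,240,19.1,11.0,11.4,19,56,N,32,84,76,385,NA,NA
2011-11-08,Tu,73,1.9,13,70,-12.2,-4.4,7.6,22,71,Y,98,660,109,489,28,NA
2013-09-16,Mo,55,1.3,21,10,-3.6,-20.7,1.8,16,64,Y,NA,NA,NA,NA,NA,NA
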