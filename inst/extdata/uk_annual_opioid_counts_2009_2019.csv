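year,registered_patients,incident_users,ltot_users,ltot_discontinuers
2009,1165440,254066,31905,1690
2010,1194284,262411,31978,1620
2011,1218921,266417,32001,1589
2012,1240969,274116,31515,1570
2013,1260446,275520,31261,1569
2014,1358015,280519,31749,1470
2015,1326781,278251,30480,1416
2016,1328107,269706,29697,1391
2017,1332717,249669,27646,1237
2018,1323147,224008,24424,1057
2019,1392118,204478,22221,875
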